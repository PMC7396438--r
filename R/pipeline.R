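## End-to-end orchestration: simulate or load structures, dock, cluster,
## annotate with restraints, filter, rescore, select, validate, report.
## Every stage failure is rethrown tagged with the stage name.

stageError <- function(stage, e) {
  stop(errorCondition(paste0("stage '", stage, "' failed: ",
                             conditionMessage(e)),
                      class = c("xlinkdockStageError", "error"),
                      stage = stage))
}

runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "xlinkdockStageError")) stop(e)
    stageError(stage, e)
  })
}

## stable short hash of the configuration (FNV-1a over its JSON form)
configHash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                      digits = NA))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Default pipeline configuration
#'
#' Either \code{simulate} parameters (a synthetic system is generated) or
#' \code{inputs} paths (receptor/ligand PDB, restraints TSV, criteria
#' YAML) drive the run; all stage parameters are exposed. The seed is
#' mandatory and controls every stochastic stage.
#'
#' @param seed integer seed.
#' @param ... overrides of the defaults (nested lists are replaced
#'   wholesale).
#' @export
defaultRunConfig <- function(seed = 1L, ...) {
  config <- list(
    seed = as.integer(seed),
    simulate = list(n_receptor = 120L, n_ligand = 23L, interface_size = 9L),
    inputs = NULL,
    docking = list(spacing = 1.2, rotations = 60L, top_n = 200L,
                   clash = 9, radius = 1.8),
    analysis = list(cutoff = 5, cluster_radius = 10, density_radius = 5),
    select = list(k = 5L),
    validate = TRUE)
  over <- list(...)
  config[names(over)] <- over
  config
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; missing fields take the defaults.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed")
  do.call(defaultRunConfig, c(list(seed = y$seed),
                              y[setdiff(names(y), "seed")]))
}

#' Run the full docking-and-screening pipeline
#'
#' Simulates (or loads) receptor and ligand, docks, clusters, annotates
#' poses with interfaces, restraint distances and rescoring, filters
#' against the criteria, selects the final models by the
#' density/score/rescore triple criterion, optionally validates the
#' ligand model, and writes all stage outputs plus a manifest to
#' \code{out_dir}. Deterministic given the configured seed.
#'
#' @param config list from \code{\link{defaultRunConfig}} or
#'   \code{\link{readRunConfig}}.
#' @param out_dir output directory.
#' @return invisibly, a list with the selected records, annotated table,
#'   poses, system and manifest.
#' @export
runPipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(stage, ...) message(sprintf("[%s] %s", stage,
                                              sprintf(...)))
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    receptor <- runStage("load", readPDB(inp$receptor))
    ligand <- runStage("load", readPDB(inp$ligand))
    restraints <- runStage("restrain", {
      if (is.null(inp$restraints) || !file.exists(inp$restraints))
        stop("restraint file not found: ", inp$restraints)
      readRestraints(inp$restraints)
    })
    criteria <- runStage("filter", readCriteria(inp$criteria))
    sys <- NULL
  } else {
    sys <- runStage("simulate", do.call(makeBlockComplex,
      c(list(seed = config$seed), config$simulate)))
    receptor <- sys@receptor
    ligand <- sys@ligand
    restraints <- sys@restraints
    criteria <- syntheticCriteria(sys)
    log("simulate", "receptor %d residues, ligand %d residues",
        nResidues(receptor), nResidues(ligand))
  }

  dk <- config$docking
  poses <- runStage("dock", {
    rot <- rotationSet(dk$rotations, seed = config$seed)
    dockSearch(receptor, ligand, rot, spacing = dk$spacing,
               blocked = criteria@blocked, top_n = dk$top_n,
               clash = dk$clash, radius = dk$radius)
  })
  log("dock", "%d poses generated", length(poses))
  writePoses(poses, file.path(out_dir, "poses.tsv"))

  an <- config$analysis
  records <- runStage("annotate", annotatePoses(
    receptor, ligand, poses, cutoff = an$cutoff,
    cluster_radius = an$cluster_radius,
    density_radius = an$density_radius,
    restraints = restraints, rescore = TRUE))
  log("annotate", "%d clusters", length(unique(records$cluster)))

  records <- runStage("filter",
                      filterPoses(records, criteria, receptor, ligand))
  passing <- passingPoses(records)
  ## integrative step: on top of the interface criteria, retained models
  ## must satisfy every cross-link spacer-arm restraint
  if (length(restraints) > 0)
    passing <- passing[passing$sat_count == length(restraints), ,
                       drop = FALSE]
  log("filter", "%d of %d poses pass", nrow(passing), nrow(records))
  ## candidate models are the cluster representatives of the passing set
  ## (highest primary score per cluster), mirroring how representative
  ## models are drawn from pose clusters
  if (nrow(passing) > 0) {
    best <- unlist(lapply(split(seq_len(nrow(passing)), passing$cluster),
                          function(ix) ix[which.max(passing$score[ix])]))
    passing <- passing[sort(best), , drop = FALSE]
  }
  exportPoseTable(records, file.path(out_dir, "pose_table.tsv"))
  exportScoreDensityPoints(records, file.path(out_dir, "score_density.tsv"))

  selected <- runStage("select",
                       selectModels(passing, config$select$k))
  log("select", "%d models selected", nrow(selected))
  selDir <- file.path(out_dir, "selected")
  dir.create(selDir, showWarnings = FALSE)
  for (i in seq_len(nrow(selected))) {
    pid <- selected$id[i]
    posed <- applyPose(ligand, poses, match(pid, poses@id))
    writePDB(mergeStructures(receptor, posed,
                             id = sprintf("model_%03d", pid)),
             file.path(selDir, sprintf("model_%03d.pdb", pid)))
  }

  validation <- NULL
  if (isTRUE(config$validate)) {
    validation <- runStage("validate", {
      prof <- verifyScore(ligand)
      dih <- ramachandranClassify(backboneDihedrals(ligand))
      out <- classifyOutcome(prof)
      utils::write.table(
        data.frame(key = dih$key, phi = dih$phi, psi = dih$psi,
                   classification = dih$classification),
        file.path(out_dir, "validation.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      out
    })
    log("validate", "ligand model graded %s (verify %.2f)",
        validation$label, validation$verifyScore)
  }

  manifest <- list(
    package = "xlinkdock",
    version = as.character(utils::packageVersion("xlinkdock")),
    seed = config$seed,
    config = config,
    config_hash = configHash(config),
    n_poses = length(poses),
    n_passing = nrow(passing),
    n_selected = nrow(selected))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(selected = selected, records = records, poses = poses,
                 system = sys, validation = validation,
                 manifest = manifest))
}
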