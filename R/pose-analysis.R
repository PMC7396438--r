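## Interface detection, leader clustering by ligand position, pose density
## and criteria-based filtering of docking poses.

#' Residue-level binding interface between two structures
#'
#' All residue pairs whose heavy-atom minimum distance is at or below the
#' cutoff. Complete by construction: every cross-structure atom pair is
#' examined.
#'
#' @param receptor,ligand_posed \linkS4class{Structure}s (the ligand in its
#'   posed placement).
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 5).
#' @return An \linkS4class{InterfaceMap}.
#' @export
interfaceResidues <- function(receptor, ligand_posed, cutoff = 5) {
  stopifnot(cutoff > 0)
  ra <- heavyAtoms(receptor)
  la <- heavyAtoms(ligand_posed)
  emptyMap <- new("InterfaceMap", receptorResidues = character(),
                  ligandResidues = character(),
                  contacts = data.frame(receptor = character(),
                                        ligand = character(),
                                        dist = numeric()),
                  cutoff = cutoff)
  if (nrow(ra) == 0 || nrow(la) == 0) return(emptyMap)
  D2 <- crossDist2(as.matrix(ra[, c("x", "y", "z")]),
                   as.matrix(la[, c("x", "y", "z")]))
  hit <- which(D2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(emptyMap)
  rk <- atomResKeys(ra)[hit[, 1L]]
  lk <- atomResKeys(la)[hit[, 2L]]
  d <- sqrt(D2[hit])
  pair <- paste(rk, lk, sep = "~")
  minPer <- tapply(d, pair, min)
  parts <- strsplit(names(minPer), "~", fixed = TRUE)
  contacts <- data.frame(
    receptor = vapply(parts, `[`, "", 1L),
    ligand = vapply(parts, `[`, "", 2L),
    dist = as.numeric(minPer), stringsAsFactors = FALSE)
  contacts <- contacts[order(contacts$receptor, contacts$ligand), ]
  rownames(contacts) <- NULL
  new("InterfaceMap",
      receptorResidues = unique(contacts$receptor),
      ligandResidues = unique(contacts$ligand),
      contacts = contacts, cutoff = cutoff)
}

## transformed ligand centroids of all poses (centroid + t by the pose
## convention)
poseCentroids <- function(poses, ligand) {
  ctr <- ligandCenter(ligand)
  sweep(poses@t, 2L, ctr, "+")
}

#' Cluster poses by ligand position (greedy leader clustering)
#'
#' Poses are visited in descending primary score (ties by pose id); each
#' pose joins the first existing cluster whose representative centroid is
#' within \code{radius}, else founds a new cluster. The representative is
#' the founding (highest-scoring) member.
#'
#' @param poses \linkS4class{PoseSet}.
#' @param ligand reference ligand \linkS4class{Structure}.
#' @param radius clustering radius, Angstrom (default 10).
#' @return list with \code{assignments} (data.frame id, cluster) and
#'   \code{clusters} (data.frame cluster, representative, n).
#' @export
clusterPoses <- function(poses, ligand, radius = 10) {
  stopifnot(radius > 0)
  n <- length(poses)
  if (n == 0L)
    return(list(assignments = data.frame(id = integer(), cluster = integer()),
                clusters = data.frame(cluster = integer(),
                                      representative = integer(),
                                      n = integer())))
  cen <- poseCentroids(poses, ligand)
  ord <- order(-poses@score, poses@id)
  leaders <- matrix(numeric(0), 0L, 3L)
  leaderIds <- integer(0)
  cluster <- integer(n)
  for (i in ord) {
    assigned <- FALSE
    if (nrow(leaders) > 0) {
      d2 <- colSums((t(leaders) - cen[i, ])^2)
      hit <- which(d2 <= radius^2)
      if (length(hit) > 0) {
        cluster[i] <- hit[1L]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      leaders <- rbind(leaders, cen[i, ])
      leaderIds <- c(leaderIds, poses@id[i])
      cluster[i] <- nrow(leaders)
    }
  }
  list(assignments = data.frame(id = poses@id, cluster = cluster),
       clusters = data.frame(cluster = seq_along(leaderIds),
                             representative = leaderIds,
                             n = as.integer(table(factor(cluster,
                               levels = seq_along(leaderIds))))))
}

#' Pose density
#'
#' Number of poses (including the pose itself) whose transformed ligand
#' centroid lies within \code{radius} of a pose's centroid -- the
#' consensus signal used together with the primary score to pick models.
#'
#' @inheritParams clusterPoses
#' @param radius density radius, Angstrom (default 10).
#' @return integer vector of per-pose counts (>= 1).
#' @export
poseDensity <- function(poses, ligand, radius = 10) {
  stopifnot(radius > 0)
  n <- length(poses)
  if (n == 0L) return(integer(0))
  cen <- poseCentroids(poses, ligand)
  D2 <- crossDist2(cen, cen)
  as.integer(rowSums(D2 <= radius^2))
}

#' Annotate docking poses into a pose table
#'
#' Computes, per pose: cluster assignment, density, interface map,
#' restraint distances and satisfied counts (when a
#' \linkS4class{RestraintSet} is given) and the energy rescore (when
#' \code{rescore = TRUE}) -- the machine twin of a per-pose properties
#' table.
#'
#' @param receptor receptor \linkS4class{Structure}.
#' @param ligand reference ligand \linkS4class{Structure}.
#' @param poses \linkS4class{PoseSet}.
#' @param cutoff interface cutoff, Angstrom.
#' @param cluster_radius,density_radius clustering/density radii; the
#'   density radius defaults to the clustering radius.
#' @param restraints optional \linkS4class{RestraintSet}.
#' @param rescore compute the detailed-energy rescore per pose.
#' @param weights rescoring weights (see \code{\link{rescoreWeights}}).
#' @param params energy parameters (see \code{\link{energyParams}}).
#' @return data.frame with columns id, cluster, density, score, rescore,
#'   sat_count, one \code{dist_<label>} column per restraint, and
#'   list-columns \code{rec_iface} / \code{lig_iface} holding the
#'   interface residue keys.
#' @export
annotatePoses <- function(receptor, ligand, poses, cutoff = 5,
                          cluster_radius = 10,
                          density_radius = cluster_radius,
                          restraints = NULL, rescore = FALSE,
                          weights = rescoreWeights(),
                          params = energyParams()) {
  n <- length(poses)
  cl <- clusterPoses(poses, ligand, cluster_radius)
  dens <- poseDensity(poses, ligand, density_radius)
  rec <- data.frame(id = poses@id,
                    cluster = cl$assignments$cluster,
                    density = if (n) dens else integer(0),
                    score = poses@score,
                    rescore = NA_real_, sat_count = NA_integer_)
  recIface <- vector("list", n)
  ligIface <- vector("list", n)
  distCols <- NULL
  if (!is.null(restraints) && length(restraints) > 0)
    distCols <- matrix(NA_real_, n, length(restraints),
                       dimnames = list(NULL,
                         paste0("dist_", restraints@links$label)))
  for (i in seq_len(n)) {
    posed <- applyPose(ligand, poses, i)
    im <- interfaceResidues(receptor, posed, cutoff)
    recIface[[i]] <- im@receptorResidues
    ligIface[[i]] <- im@ligandResidues
    if (!is.null(distCols)) {
      rr <- evaluateRestraints(restraints, receptor, posed)
      distCols[i, ] <- rr$distance
      rec$sat_count[i] <- sum(rr$satisfied)
    }
    if (rescore)
      rec$rescore[i] <- rescorePose(energyTerms(receptor, posed, params),
                                    weights)
  }
  if (!is.null(distCols)) rec <- cbind(rec, as.data.frame(distCols))
  rec$rec_iface <- I(recIface)
  rec$lig_iface <- I(ligIface)
  rec
}

#' Validate filter criteria against the structures
#'
#' Criteria referencing residues absent from the receptor or ligand are a
#' configuration error; the offending keys are listed.
#'
#' @param criteria \linkS4class{FilterCriteria}.
#' @param receptor,ligand \linkS4class{Structure}s.
#' @export
validateCriteria <- function(criteria, receptor, ligand) {
  recKeys <- residueKeys(receptor)
  ligKeys <- residueKeys(ligand)
  bad <- c(setdiff(c(criteria@requiredReceptorInterface, criteria@blocked),
                   recKeys),
           setdiff(c(criteria@requiredLigandDomain,
                     criteria@orientationRequired,
                     criteria@orientationForbidden), ligKeys))
  if (length(bad) > 0)
    stop("criteria reference residues absent from the structures: ",
         paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' Filter annotated poses against experiment-derived criteria
#'
#' A pose passes iff (i) every required receptor residue is in its
#' interface, (ii) at least \code{minDomainFraction} of its ligand
#' interface residues lie in the required ligand domain, and (iii) the
#' orientation sets meet their minimum/maximum interface counts. Failures
#' are recorded per criterion in \code{fail_reasons}; \code{passed} is
#' TRUE iff the reasons are empty.
#'
#' @param records pose table from \code{\link{annotatePoses}}.
#' @param criteria \linkS4class{FilterCriteria}.
#' @param receptor,ligand optional \linkS4class{Structure}s; when given,
#'   the criteria are validated against them first.
#' @return the records with \code{passed} and \code{fail_reasons} columns
#'   filled in (all rows retained; subset with \code{\link{passingPoses}}).
#' @export
filterPoses <- function(records, criteria, receptor = NULL, ligand = NULL) {
  if (!is.null(receptor) && !is.null(ligand))
    validateCriteria(criteria, receptor, ligand)
  n <- nrow(records)
  passed <- logical(n)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    ri <- records$rec_iface[[i]]
    li <- records$lig_iface[[i]]
    fail <- character(0)
    missing <- setdiff(criteria@requiredReceptorInterface, ri)
    if (length(missing) > 0)
      fail <- c(fail, paste0("required_receptor_interface:",
                             paste(missing, collapse = ",")))
    if (length(criteria@requiredLigandDomain) > 0) {
      frac <- if (length(li) == 0) 0
              else mean(li %in% criteria@requiredLigandDomain)
      if (frac < criteria@minDomainFraction)
        fail <- c(fail, sprintf("ligand_domain_fraction:%.2f", frac))
    }
    if (length(criteria@orientationRequired) > 0) {
      cnt <- sum(criteria@orientationRequired %in% li)
      if (cnt < criteria@orientationRequiredMin)
        fail <- c(fail, sprintf("orientation_required:%d", cnt))
    }
    if (length(criteria@orientationForbidden) > 0) {
      cnt <- sum(criteria@orientationForbidden %in% li)
      if (cnt > criteria@orientationForbiddenMax)
        fail <- c(fail, sprintf("orientation_forbidden:%d", cnt))
    }
    passed[i] <- length(fail) == 0L
    reasons[[i]] <- fail
  }
  records$passed <- passed
  records$fail_reasons <- I(reasons)
  records
}

#' Passing subset of a filtered pose table
#' @param records output of \code{\link{filterPoses}}.
#' @export
passingPoses <- function(records) {
  if (is.null(records$passed)) stop("records have not been filtered yet")
  records[records$passed, , drop = FALSE]
}

flattenListCol <- function(x) vapply(x, paste, "", collapse = ";")

#' Export an annotated pose table as TSV
#'
#' List columns (interface keys, failure reasons) are flattened with
#' \code{";"} separators.
#'
#' @param records pose table.
#' @param path output file.
#' @export
exportPoseTable <- function(records, path) {
  flat <- records
  for (col in c("rec_iface", "lig_iface", "fail_reasons"))
    if (!is.null(flat[[col]]))
      flat[[col]] <- flattenListCol(flat[[col]])
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname exportPoseTable
#' @export
readPoseTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Export (score, density, cluster) triples for 3D plotting
#'
#' @param records pose table.
#' @param path output file.
#' @export
exportScoreDensityPoints <- function(records, path) {
  utils::write.table(records[, c("score", "density", "cluster")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write filter criteria as YAML
#'
#' @param criteria \linkS4class{FilterCriteria}.
#' @param path YAML file.
#' @export
writeCriteria <- function(criteria, path) {
  yaml::write_yaml(list(
    required_receptor_interface = as.list(criteria@requiredReceptorInterface),
    required_ligand_domain = as.list(criteria@requiredLigandDomain),
    min_domain_fraction = criteria@minDomainFraction,
    orientation_required = as.list(criteria@orientationRequired),
    orientation_required_min = criteria@orientationRequiredMin,
    orientation_forbidden = as.list(criteria@orientationForbidden),
    orientation_forbidden_max = criteria@orientationForbiddenMax,
    blocked = as.list(criteria@blocked)), path)
  invisible(path)
}

#' @rdname writeCriteria
#' @export
readCriteria <- function(path) {
  y <- yaml::read_yaml(path)
  FilterCriteria(
    requiredReceptorInterface = unlist(y$required_receptor_interface),
    requiredLigandDomain = unlist(y$required_ligand_domain),
    minDomainFraction = y$min_domain_fraction %||% 0.5,
    orientationRequired = unlist(y$orientation_required),
    orientationRequiredMin = y$orientation_required_min %||% 1L,
    orientationForbidden = unlist(y$orientation_forbidden),
    orientationForbiddenMax = y$orientation_forbidden_max %||% 0L,
    blocked = unlist(y$blocked))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
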