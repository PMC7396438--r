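## Cross-link restraint evaluation: residue-level photo-cross-links and
## chemical cross-links with spacer-arm maximum distances, measured on
## posed complexes. Satisfaction is inclusive (distance <= max_dist,
## with a 1e-9 A tolerance for floating-point arithmetic): a spacer
## length is a maximum reach.

XL_TOL <- 1e-9

#' Anchor atoms of a residue for a cross-link kind
#'
#' Amine-amine links anchor on the lysine side-chain amine (NZ);
#' amine-sulfhydryl links anchor on SG for cysteines and NZ for lysines
#' (a residue with neither -- e.g. a wild-type position where the
#' experiment used a cysteine mutant -- falls back to CB, flagged in the
#' \code{"note"} attribute); photo-cross-link sites are residue-level and
#' anchor on CB, falling back to CA.
#'
#' @param res atom data.frame of one residue.
#' @param kind one of \code{"photo_pBpa"}, \code{"amine_amine"},
#'   \code{"amine_sulfhydryl"}.
#' @return atom data.frame of the anchors, possibly with attribute
#'   \code{"note"}.
#' @export
anchorAtoms <- function(res, kind) {
  key <- resKey(res$chain[1L], res$resno[1L], res$insert[1L])
  pick <- function(name) res[res$elety %in% name, , drop = FALSE]
  note <- NULL
  out <- switch(kind,
    amine_amine = pick("NZ"),
    amine_sulfhydryl = {
      a <- pick("SG")
      if (nrow(a) == 0) a <- pick("NZ")
      if (nrow(a) == 0) {
        a <- pick("CB")
        if (nrow(a) > 0)
          note <- paste0("no SG/NZ in ", key, "; CB used as anchor")
      }
      a
    },
    photo_pBpa = {
      a <- pick("CB")
      if (nrow(a) == 0) a <- pick("CA")
      a
    },
    stop("unknown restraint kind: ", kind))
  if (nrow(out) == 0)
    stop("anchor error: residue ", key, " (", res$resid[1L],
         ") has no anchor atom for kind ", kind)
  attr(out, "note") <- note
  out
}

## one residue's atoms by (chain, resno); error names the residue
.anchorResidue <- function(s, chain, resno, role) {
  res <- residueAtoms(s, resKey(chain, resno))
  if (is.null(res))
    stop("anchor error: ", role, " residue ", resKey(chain, resno),
         " not found in structure ", structureId(s))
  res
}

#' Evaluate one cross-link restraint on a posed complex
#'
#' The measured distance is the minimum over eligible anchor-atom pairs.
#' A wildcard ligand anchor (\code{ligand_res == "*"}) scans every lysine
#' of the ligand (restricted to \code{ligand_chain} unless that is also
#' \code{"*"}) and reports all partner residues within \code{max_dist},
#' sorted by distance.
#'
#' @param link one row of \code{restraintLinks()}.
#' @param receptor receptor \linkS4class{Structure}.
#' @param ligand_posed posed ligand \linkS4class{Structure}.
#' @return list(label, kind, distance, max_dist, satisfied, partners,
#'   note).
#' @export
evaluateRestraint <- function(link, receptor, ligand_posed) {
  recRes <- .anchorResidue(receptor, link$receptor_chain, link$receptor_res,
                           "receptor")
  recAnchor <- anchorAtoms(recRes, link$kind)
  note <- attr(recAnchor, "note")
  A <- as.matrix(recAnchor[, c("x", "y", "z")])
  la <- atomData(ligand_posed)
  if (identical(link$ligand_res, "*")) {
    cand <- la[la$resid == "LYS", , drop = FALSE]
    if (!identical(link$ligand_chain, "*"))
      cand <- cand[cand$chain == link$ligand_chain, , drop = FALSE]
    if (nrow(cand) == 0)
      stop("anchor error: ligand has no lysine for wildcard restraint ",
           link$label)
    keys <- unique(atomResKeys(cand))
    dists <- vapply(keys, function(k) {
      res <- cand[atomResKeys(cand) == k, , drop = FALSE]
      anc <- anchorAtoms(res, link$kind)
      sqrt(min(crossDist2(A, as.matrix(anc[, c("x", "y", "z")]))))
    }, numeric(1L))
    ord <- order(dists)
    within <- dists[ord] <= link$max_dist + XL_TOL
    partners <- names(dists)[ord][within]
    dist <- min(dists)
  } else {
    ligRes <- .anchorResidue(ligand_posed, link$ligand_chain,
                             as.integer(link$ligand_res), "ligand")
    ligAnchor <- anchorAtoms(ligRes, link$kind)
    if (!is.null(attr(ligAnchor, "note")))
      note <- c(note, attr(ligAnchor, "note"))
    dist <- sqrt(min(crossDist2(A, as.matrix(ligAnchor[, c("x", "y", "z")]))))
    partners <- if (dist <= link$max_dist + XL_TOL)
      resKey(ligRes$chain[1L], ligRes$resno[1L]) else character(0)
  }
  list(label = link$label, kind = link$kind, distance = dist,
       max_dist = link$max_dist,
       satisfied = dist <= link$max_dist + XL_TOL,
       partners = partners, note = note)
}

#' Evaluate a whole restraint set on one posed complex
#'
#' @param restraints \linkS4class{RestraintSet}.
#' @param receptor,ligand_posed \linkS4class{Structure}s.
#' @return data.frame(label, kind, distance, max_dist, satisfied,
#'   n_partners, partners, note) -- one row per restraint.
#' @export
evaluateRestraints <- function(restraints, receptor, ligand_posed) {
  links <- restraintLinks(restraints)
  rows <- lapply(seq_len(nrow(links)), function(i)
    evaluateRestraint(links[i, ], receptor, ligand_posed))
  data.frame(
    label = vapply(rows, `[[`, "", "label"),
    kind = vapply(rows, `[[`, "", "kind"),
    distance = vapply(rows, `[[`, 0, "distance"),
    max_dist = vapply(rows, `[[`, 0, "max_dist"),
    satisfied = vapply(rows, `[[`, TRUE, "satisfied"),
    n_partners = vapply(rows, function(r) length(r$partners), 0L),
    partners = vapply(rows, function(r) paste(r$partners, collapse = ";"),
                      ""),
    note = vapply(rows, function(r)
      paste(r$note %||% character(0), collapse = ";"), ""),
    stringsAsFactors = FALSE)
}

#' Restraint distances for every pose
#'
#' @param poses \linkS4class{PoseSet}.
#' @param restraints \linkS4class{RestraintSet}.
#' @param receptor receptor \linkS4class{Structure}.
#' @param ligand reference ligand \linkS4class{Structure}.
#' @return list with \code{distances} (pose x restraint matrix, columns
#'   named by label), \code{satisfied} (logical matrix) and
#'   \code{sat_count} (per-pose satisfied counts, usable as a filter key).
#' @export
annotateRestraints <- function(poses, restraints, receptor, ligand) {
  n <- length(poses)
  m <- length(restraints)
  distances <- matrix(NA_real_, n, m,
                      dimnames = list(NULL, restraints@links$label))
  satisfied <- matrix(NA, n, m, dimnames = dimnames(distances))
  for (i in seq_len(n)) {
    rep <- evaluateRestraints(restraints, receptor, applyPose(ligand, poses, i))
    distances[i, ] <- rep$distance
    satisfied[i, ] <- rep$satisfied
  }
  list(distances = distances, satisfied = satisfied,
       sat_count = as.integer(rowSums(satisfied)))
}

#' Read / write restraints as TSV
#'
#' Columns: kind, receptor_chain, receptor_res, ligand_chain, ligand_res,
#' max_dist, label; \code{"*"} marks a wildcard ligand anchor.
#'
#' @param restraints \linkS4class{RestraintSet}.
#' @param path file path.
#' @export
writeRestraints <- function(restraints, path) {
  utils::write.table(restraintLinks(restraints), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRestraints
#' @export
readRestraints <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(ligand_res = "character",
                                        ligand_chain = "character",
                                        receptor_chain = "character"))
  RestraintSet(d)
}
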