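#' @include AllClasses.R
NULL

#' Accessors for xlinkdock S4 classes
#'
#' \code{atomData} returns the atom table of a \linkS4class{Structure};
#' \code{structureId} its label; \code{chainIds} its chain identifiers;
#' \code{residueKeys} the unique \code{"chain:resno"} keys in file order;
#' \code{nResidues} the residue count; \code{coords} the n x 3 coordinate
#' matrix. Pose accessors return the corresponding \linkS4class{PoseSet}
#' slots.
#'
#' @param x object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))
#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))
#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("poseQuaternions", function(x) standardGeneric("poseQuaternions"))
#' @rdname accessors
#' @export
setGeneric("poseTranslations", function(x) standardGeneric("poseTranslations"))
#' @rdname accessors
#' @export
setGeneric("poseScores", function(x) standardGeneric("poseScores"))
#' @rdname accessors
#' @export
setGeneric("poseIds", function(x) standardGeneric("poseIds"))
#' @rdname accessors
#' @export
setGeneric("restraintLinks", function(x) standardGeneric("restraintLinks"))

## residue key helpers ------------------------------------------------------

resKey <- function(chain, resno, insert = "") {
  ins <- ifelse(is.na(insert) | insert == "", "", insert)
  paste0(chain, ":", resno, ins)
}

atomResKeys <- function(atoms) resKey(atoms$chain, atoms$resno, atoms$insert)

heavyAtoms <- function(x) {
  a <- if (is(x, "Structure")) x@atoms else x
  a[a$element != "H", , drop = FALSE]
}

## Structure methods --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("atomData", "Structure", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("structureId", "Structure", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("chainIds", "Structure", function(x) unique(x@atoms$chain))
#' @rdname accessors
#' @export
setMethod("residueKeys", "Structure", function(x) unique(atomResKeys(x@atoms)))
#' @rdname accessors
#' @export
setMethod("nResidues", "Structure", function(x) length(residueKeys(x)))
#' @rdname accessors
#' @export
setMethod("coords", "Structure", function(x)
  as.matrix(x@atoms[, c("x", "y", "z")]))

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure \"", object@id, "\": ", nrow(a), " atoms, ",
      nResidues(object), " residues, chains: ",
      paste(unique(a$chain), collapse = ", "), "\n", sep = "")
})

## PoseSet methods ----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("poseQuaternions", "PoseSet", function(x) x@q)
#' @rdname accessors
#' @export
setMethod("poseTranslations", "PoseSet", function(x) x@t)
#' @rdname accessors
#' @export
setMethod("poseScores", "PoseSet", function(x) x@score)
#' @rdname accessors
#' @export
setMethod("poseIds", "PoseSet", function(x) x@id)

#' @export
setMethod("length", "PoseSet", function(x) length(x@score))

#' @export
setMethod("[", "PoseSet", function(x, i, j, ..., drop = TRUE) {
  PoseSet(x@q[i, , drop = FALSE], x@t[i, , drop = FALSE],
          x@score[i], x@id[i])
})

#' @export
setMethod("as.data.frame", "PoseSet", function(x, ...) {
  data.frame(id = x@id, x@q, x@t, score = x@score)
})

setMethod("show", "PoseSet", function(object) {
  cat("PoseSet with", length(object), "poses")
  if (length(object) > 0)
    cat("; score range [", min(object@score), ", ",
        max(object@score), "]", sep = "")
  cat("\n")
})

## RestraintSet methods -----------------------------------------------------

#' @rdname accessors
#' @export
setMethod("restraintLinks", "RestraintSet", function(x) x@links)

#' @export
setMethod("length", "RestraintSet", function(x) nrow(x@links))

setMethod("show", "RestraintSet", function(object) {
  d <- object@links
  cat("RestraintSet with", nrow(d), "cross-links")
  if (nrow(d) > 0)
    cat(" (", paste(sprintf("%s x%d", names(table(d$kind)), table(d$kind)),
                    collapse = ", "), ")", sep = "")
  cat("\n")
})

## other show methods -------------------------------------------------------

setMethod("show", "DockGrid", function(object) {
  cells <- object@cells
  cat("DockGrid ", paste(object@dims, collapse = "x"), " @ ",
      object@spacing, " A: ", sum(cells == 1L), " surface, ",
      sum(cells == 2L), " core cells\n", sep = "")
})

setMethod("show", "InterfaceMap", function(object) {
  cat("InterfaceMap (cutoff ", object@cutoff, " A): ",
      length(object@receptorResidues), " receptor x ",
      length(object@ligandResidues), " ligand residues, ",
      nrow(object@contacts), " contact pairs\n", sep = "")
})

setMethod("show", "FilterCriteria", function(object) {
  cat("FilterCriteria:\n",
      "  required receptor interface: ",
      paste(object@requiredReceptorInterface, collapse = ", "), "\n",
      "  ligand domain (", length(object@requiredLigandDomain),
      " residues), min fraction ", object@minDomainFraction, "\n",
      "  orientation: >=", object@orientationRequiredMin, " of ",
      length(object@orientationRequired), " required, <=",
      object@orientationForbiddenMax, " of ",
      length(object@orientationForbidden), " forbidden\n", sep = "")
})

setMethod("show", "SyntheticSystem", function(object) {
  cat("SyntheticSystem (seed ", object@seed, "): receptor ",
      nResidues(object@receptor), " residues / ligand ",
      nResidues(object@ligand), " residues, ",
      length(object@restraints), " planted restraints, ",
      length(object@blockedResidues), " blocked residues\n", sep = "")
})

setMethod("show", "VerifyProfile", function(object) {
  cat("VerifyProfile: ", nrow(object@residues), " residues, verify score ",
      round(object@verifyScore, 2), " (expected high ",
      round(object@expectedHigh, 2), ", low ",
      round(object@expectedLow, 2), ")\n", sep = "")
})
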