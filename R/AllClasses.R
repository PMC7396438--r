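#' @import methods
NULL

ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "element",
               "x", "y", "z")

.validStructure <- function(object) {
  a <- object@atoms
  msg <- character()
  if (!all(ATOM_COLS %in% names(a)))
    msg <- c(msg, paste("atoms must have columns:",
                        paste(ATOM_COLS, collapse = ", ")))
  else {
    if (nrow(a) > 0) {
      if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
        msg <- c(msg, "atom coordinates must be finite")
      if (any(!nzchar(a$elety)))
        msg <- c(msg, "atom names must be non-empty")
      if (any(!nzchar(a$chain)))
        msg <- c(msg, "chain identifiers must be non-empty")
    }
  }
  if (length(msg)) msg else TRUE
}

#' Structure: chain/residue/atom coordinate model
#'
#' A flat atom table (one row per atom) grouped implicitly into residues by
#' \code{(chain, resno, insert)} and into chains by \code{chain}. Coordinates
#' are in Angstrom, in the frame of the source file; residue numbering is
#' taken as-is (no renumbering).
#'
#' @slot id character label.
#' @slot atoms data.frame with columns chain, resno, insert, resid, elety,
#'   element, x, y, z.
#' @slot metadata free-form list.
#' @export
setClass("Structure",
         representation(id = "character", atoms = "data.frame",
                        metadata = "list"),
         prototype(id = "structure", metadata = list()),
         validity = .validStructure)

#' Construct a Structure from an atom table
#'
#' @param atoms data.frame with the columns documented in
#'   \linkS4class{Structure}; \code{insert} and \code{element} are filled in
#'   if absent (element inferred from the first letter of the atom name).
#' @param id label.
#' @param metadata free-form list.
#' @return A \linkS4class{Structure}.
#' @export
Structure <- function(atoms, id = "structure", metadata = list()) {
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$element))
    atoms$element <- guessElement(atoms$elety)
  atoms <- atoms[ATOM_COLS]
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  new("Structure", id = id, atoms = atoms, metadata = metadata)
}

## element symbol from a PDB atom name (good enough for protein atoms)
guessElement <- function(elety) {
  e <- sub("^[0-9']*", "", elety)
  two <- toupper(substr(e, 1L, 2L))
  one <- toupper(substr(e, 1L, 1L))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "NA", "CA") &
           nchar(elety) == 2L & elety %in% c("FE", "ZN", "MG", "MN", "SE"),
         two, one)
}

.validPoseSet <- function(object) {
  n <- length(object@score)
  msg <- character()
  if (nrow(object@q) != n || nrow(object@t) != n || length(object@id) != n)
    msg <- c(msg, "q, t, score and id must agree in length")
  if (ncol(object@q) != 4L) msg <- c(msg, "q must have 4 columns")
  if (ncol(object@t) != 3L) msg <- c(msg, "t must have 3 columns")
  if (n > 0 && any(abs(sqrt(rowSums(object@q^2)) - 1) > 1e-9))
    msg <- c(msg, "quaternions must have unit norm (tol 1e-9)")
  if (length(msg)) msg else TRUE
}

#' PoseSet: rigid placements of a ligand
#'
#' Each pose is a rotation (unit quaternion, applied about the ligand
#' reference centroid) plus a translation in Angstrom, with an attached
#' primary (shape-complementarity) score. The transformed ligand centroid is
#' therefore \code{centroid + t}, which is what clustering and density use
#' as "the position of the ligand".
#'
#' @slot q n x 4 matrix of unit quaternions (qw,qx,qy,qz).
#' @slot t n x 3 matrix of translations (Angstrom).
#' @slot score numeric primary scores.
#' @slot id integer pose identifiers.
#' @export
setClass("PoseSet",
         representation(q = "matrix", t = "matrix", score = "numeric",
                        id = "integer"),
         validity = .validPoseSet)

#' Construct a PoseSet
#'
#' @param q n x 4 matrix (or length-4 vector) of unit quaternions.
#' @param t n x 3 matrix (or length-3 vector) of translations.
#' @param score numeric scores (default 0).
#' @param id integer ids (default sequential).
#' @export
PoseSet <- function(q, t, score = NULL, id = NULL) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4L, byrow = TRUE)
  if (is.null(dim(t))) t <- matrix(t, ncol = 3L, byrow = TRUE)
  n <- nrow(q)
  if (is.null(score)) score <- rep(0, n)
  if (is.null(id)) id <- seq_len(n)
  dimnames(q) <- list(NULL, c("qw", "qx", "qy", "qz"))
  dimnames(t) <- list(NULL, c("tx", "ty", "tz"))
  names(score) <- NULL
  new("PoseSet", q = q, t = t, score = as.numeric(score),
      id = as.integer(id))
}

#' Identity pose (no rotation, no translation)
#' @param score score to attach (default 0).
#' @export
identityPose <- function(score = 0) {
  PoseSet(c(1, 0, 0, 0), c(0, 0, 0), score = score, id = 1L)
}

#' DockGrid: discretised occupancy grid of a structure
#'
#' Cells are labelled 0 (empty), 1 (surface: occupied with at least one
#' empty 6-neighbour, grid boundary counting as empty) or 2 (core).
#'
#' @slot origin corner of the grid (Angstrom); cell (i,j,k) has its centre
#'   at \code{origin + (c(i,j,k) - 0.5) * spacing}.
#' @slot spacing cell edge length, Angstrom.
#' @slot dims integer dimensions.
#' @slot cells integer 3D array of labels.
#' @export
setClass("DockGrid",
         representation(origin = "numeric", spacing = "numeric",
                        dims = "integer", cells = "array"),
         validity = function(object) {
           if (any(object@dims < 1L)) return("dims must be positive")
           if (!identical(dim(object@cells), as.integer(object@dims)))
             return("cells array does not match dims")
           TRUE
         })

#' InterfaceMap: residue contacts across a binding interface
#'
#' @slot receptorResidues character residue keys ("chain:resno").
#' @slot ligandResidues character residue keys.
#' @slot contacts data.frame(receptor, ligand, dist) of residue pairs with
#'   heavy-atom minimum distance at or below the cutoff used.
#' @slot cutoff the cutoff (Angstrom) the map was computed with.
#' @export
setClass("InterfaceMap",
         representation(receptorResidues = "character",
                        ligandResidues = "character",
                        contacts = "data.frame", cutoff = "numeric"))

RESTRAINT_KINDS <- c("photo_pBpa", "amine_amine", "amine_sulfhydryl")

.validRestraintSet <- function(object) {
  d <- object@links
  need <- c("kind", "receptor_chain", "receptor_res", "ligand_chain",
            "ligand_res", "max_dist", "label")
  msg <- character()
  if (!all(need %in% names(d)))
    msg <- c(msg, paste("links must have columns:", paste(need, collapse = ", ")))
  else if (nrow(d) > 0) {
    if (!all(d$kind %in% RESTRAINT_KINDS))
      msg <- c(msg, paste("kind must be one of:", paste(RESTRAINT_KINDS, collapse = ", ")))
    if (!all(d$max_dist > 0)) msg <- c(msg, "max_dist must be positive")
    if (any(is.na(d$receptor_res)))
      msg <- c(msg, "receptor anchors must be residue numbers (no wildcards)")
  }
  if (length(msg)) msg else TRUE
}

#' RestraintSet: typed cross-link restraints
#'
#' Holds residue-level photo-cross-links (pBpa capture sites) and chemical
#' cross-links with spacer-arm maximum distances (amine-amine 12 A,
#' amine-sulfhydryl 6.8 A are the canonical reagent arm lengths). The ligand
#' anchor may be the wildcard \code{"*"} meaning "any lysine of the ligand".
#'
#' @slot links data.frame(kind, receptor_chain, receptor_res, ligand_chain,
#'   ligand_res, max_dist, label).
#' @export
setClass("RestraintSet", representation(links = "data.frame"),
         validity = .validRestraintSet)

#' Construct a RestraintSet
#' @param links data.frame as documented for \linkS4class{RestraintSet};
#'   \code{ligand_res} is a character column ("*" allowed).
#' @export
RestraintSet <- function(links) {
  if (any(as.character(links$receptor_res) == "*"))
    stop("wildcard anchors are only allowed on the ligand side")
  links$receptor_res <- as.integer(links$receptor_res)
  links$ligand_res <- as.character(links$ligand_res)
  links$kind <- as.character(links$kind)
  rownames(links) <- NULL
  new("RestraintSet", links = links)
}

#' FilterCriteria: experiment-derived pose filter
#'
#' Encodes the interface requirements used to screen docking poses:
#' receptor residues that must lie in the binding interface (the
#' photo-cross-linking capture sites), a ligand docking domain that must
#' carry at least \code{minDomainFraction} of the ligand interface
#' residues, orientation residue sets with minimum/maximum interface
#' counts, and receptor residues blocked from docking altogether.
#' All residues are keyed \code{"chain:resno"}.
#'
#' @export
setClass("FilterCriteria",
         representation(requiredReceptorInterface = "character",
                        requiredLigandDomain = "character",
                        minDomainFraction = "numeric",
                        orientationRequired = "character",
                        orientationRequiredMin = "integer",
                        orientationForbidden = "character",
                        orientationForbiddenMax = "integer",
                        blocked = "character"),
         validity = function(object) {
           f <- object@minDomainFraction
           if (length(f) != 1L || f < 0 || f > 1)
             return("minDomainFraction must be a single value in [0, 1]")
           TRUE
         })

#' Construct FilterCriteria
#'
#' With all defaults the criteria are empty and every pose passes.
#'
#' @param requiredReceptorInterface receptor residue keys that must be in
#'   the interface.
#' @param requiredLigandDomain ligand residue keys of the docking domain.
#' @param minDomainFraction minimum fraction of ligand interface residues
#'   inside the domain (default 0.5, i.e. the ligand binds "mainly" through
#'   the domain).
#' @param orientationRequired,orientationRequiredMin ligand residue keys of
#'   the receptor-facing side and the minimum number of them required in
#'   the interface.
#' @param orientationForbidden,orientationForbiddenMax ligand residue keys
#'   of the away-facing side and the maximum number tolerated in the
#'   interface.
#' @param blocked receptor residue keys excluded from the docking surface.
#' @export
FilterCriteria <- function(requiredReceptorInterface = character(),
                           requiredLigandDomain = character(),
                           minDomainFraction = 0.5,
                           orientationRequired = character(),
                           orientationRequiredMin = 1L,
                           orientationForbidden = character(),
                           orientationForbiddenMax = 0L,
                           blocked = character()) {
  new("FilterCriteria",
      requiredReceptorInterface = as.character(requiredReceptorInterface),
      requiredLigandDomain = as.character(requiredLigandDomain),
      minDomainFraction = minDomainFraction,
      orientationRequired = as.character(orientationRequired),
      orientationRequiredMin = as.integer(orientationRequiredMin),
      orientationForbidden = as.character(orientationForbidden),
      orientationForbiddenMax = as.integer(orientationForbiddenMax),
      blocked = as.character(blocked))
}

#' SyntheticSystem: toy receptor-ligand complex with ground truth
#'
#' @slot receptor multi-chain receptor \linkS4class{Structure} with a
#'   designated blocked (membrane-embedded analogue) region.
#' @slot ligand ligand \linkS4class{Structure} in its native placement.
#' @slot nativePose identity \linkS4class{PoseSet} (length 1).
#' @slot restraints planted \linkS4class{RestraintSet}, all satisfied in the
#'   native pose.
#' @slot blockedResidues receptor residue keys of the blocked region.
#' @slot ligandDomain ligand residue keys of the docking domain.
#' @slot orientationSets list(proximal=, distal=) of disjoint ligand residue
#'   key sets (receptor-facing and away-facing sides).
#' @slot seed integer generator seed.
#' @slot metadata list (lattice spacing, pocket geometry, anchors).
#' @export
setClass("SyntheticSystem",
         representation(receptor = "Structure", ligand = "Structure",
                        nativePose = "PoseSet", restraints = "RestraintSet",
                        blockedResidues = "character",
                        ligandDomain = "character",
                        orientationSets = "list", seed = "integer",
                        metadata = "list"),
         validity = function(object) {
           os <- object@orientationSets
           if (!all(c("proximal", "distal") %in% names(os)))
             return("orientationSets needs elements 'proximal' and 'distal'")
           if (length(intersect(os$proximal, os$distal)) > 0)
             return("orientation sets must be disjoint")
           TRUE
         })

.validVerifyProfile <- function(object) {
  msg <- character()
  if (nrow(object@residues) > 0) {
    if (abs(object@verifyScore - sum(object@residues$score)) > 1e-6)
      msg <- c(msg, "verifyScore must equal the sum of per-residue scores")
  }
  if (object@expectedHigh > 0 &&
      abs(object@expectedLow - 0.45 * object@expectedHigh) > 1e-9)
    msg <- c(msg, "expectedLow must be 0.45 * expectedHigh")
  if (length(msg)) msg else TRUE
}

#' VerifyProfile: 3D-1D environment-profile assessment of a model
#'
#' @slot residues per-residue data.frame(key, resid, burial, polarity, ss,
#'   envClass, score).
#' @slot verifyScore sum of per-residue 3D-1D scores.
#' @slot expectedHigh length-calibrated expected score of a correct
#'   structure.
#' @slot expectedLow 45 percent of expectedHigh; models scoring below it are
#'   graded grossly misfolded.
#' @export
setClass("VerifyProfile",
         representation(residues = "data.frame", verifyScore = "numeric",
                        expectedHigh = "numeric", expectedLow = "numeric"),
         validity = .validVerifyProfile)
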