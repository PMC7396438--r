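## PDB coordinate input/output and selection/geometry primitives.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Default residue alias table
#'
#' Maps non-standard 3-letter codes (selenomethionine, selenocysteine,
#' pyrrolysine and a benzophenone photo-probe site modelled on its parent)
#' to the parent amino acid. The shipped table lives in
#' \code{inst/extdata/residue_aliases.tsv} and can be replaced by any
#' two-column (code, parent) text file.
#'
#' @param path optional path to an alias table.
#' @return named character vector code -> parent.
#' @export
residueAliases <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "residue_aliases.tsv",
                        package = "xlinkdock")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(tab$parent, tab$code)
}

#' Read a PDB file into a Structure
#'
#' Parses fixed-column ATOM/HETATM records through \pkg{bio3d}. Only rows
#' whose residue type is one of the twenty standard amino acids, or is
#' mapped to one by the alias table, are kept (the alias's parent type is
#' substituted). For alternate locations the first-listed location of each
#' atom is retained. Hydrogens are kept in the table; all distance and
#' grid operations use heavy atoms only.
#'
#' @param path PDB file.
#' @param aliases named character vector mapping non-standard residue codes
#'   to parent amino acids (default \code{residueAliases()}).
#' @param id structure label (default: file name).
#' @return A \linkS4class{Structure}.
#' @export
readPDB <- function(path, aliases = residueAliases(), id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(isAtom))
    stop("no ATOM records in ", path)
  ## validate coordinate fields before handing off to the parser so a
  ## malformed file fails with the offending line number
  for (i in which(isAtom)) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    v <- suppressWarnings(as.numeric(fields))
    if (any(is.na(v)))
      stop("unparsable coordinate field at line ", i, " of ", path)
  }
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- " "
  ## altloc: keep the first-listed location of each atom
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  a <- a[!duplicated(key), , drop = FALSE]
  ## residue types: standard amino acids, or aliases mapped to parents
  isStd <- a$resid %in% STANDARD_AA
  isAlias <- a$resid %in% names(aliases)
  a <- a[isStd | isAlias, , drop = FALSE]
  if (nrow(a) == 0)
    stop("no standard amino-acid residues in ", path)
  aliasIdx <- a$resid %in% names(aliases)
  a$resid[aliasIdx] <- unname(aliases[a$resid[aliasIdx]])
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- guessElement(a$elety)
  elem[is.na(elem) | elem == ""] <- guessElement(a$elety[is.na(elem) | elem == ""])
  atoms <- data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
                      resid = a$resid, elety = a$elety,
                      element = toupper(trimws(elem)),
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  Structure(atoms, id = if (is.null(id)) basename(path) else id,
            metadata = list(source = path))
}

#' Write a Structure to a PDB file
#'
#' Emits fixed-column ATOM records, one TER per chain and a final END.
#' \code{readPDB(writePDB(s))} reproduces coordinates to three decimals
#' (the PDB column precision).
#'
#' @param s \linkS4class{Structure} with at least one atom.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePDB <- function(s, path) {
  a <- atomData(s)
  if (nrow(a) == 0) stop("cannot write an empty Structure")
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in unique(a$chain)) {
    ca <- a[a$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(ca))) {
      serial <- serial + 1L
      name <- ca$elety[i]
      namef <- if (nchar(name) >= 4L) substr(name, 1L, 4L)
               else sprintf(" %-3s", name)
      writeLines(sprintf(
        "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, namef, ca$resid[i], substr(ch, 1L, 1L),
        ca$resno[i] %% 10000L,
        ifelse(ca$insert[i] == "", " ", ca$insert[i]),
        ca$x[i], ca$y[i], ca$z[i], 1.00, 0.00,
        substr(ca$element[i], 1L, 2L)), con)
    }
    serial <- serial + 1L
    last <- ca[nrow(ca), ]
    writeLines(sprintf("TER   %5d      %3s %1s%4d", serial %% 100000L,
                       last$resid, substr(ch, 1L, 1L),
                       last$resno %% 10000L), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select residues from a chain by number
#'
#' Missing numbers are reported, never silently dropped.
#'
#' @param s \linkS4class{Structure}.
#' @param chain chain identifier (must exist).
#' @param numbers integer residue numbers.
#' @return list with \code{residues} (named list of per-residue atom
#'   data.frames, in the order of \code{numbers}) and \code{missing}
#'   (numbers absent from the chain).
#' @export
selectResidues <- function(s, chain, numbers) {
  a <- atomData(s)
  if (!chain %in% a$chain)
    stop("unknown chain: ", chain)
  ca <- a[a$chain == chain, , drop = FALSE]
  numbers <- as.integer(numbers)
  found <- numbers[numbers %in% ca$resno]
  res <- lapply(found, function(n) ca[ca$resno == n, , drop = FALSE])
  names(res) <- found
  list(residues = res, missing = setdiff(numbers, found))
}

## atom table of one residue keyed "chain:resno" (NULL if absent)
residueAtoms <- function(s, key) {
  a <- atomData(s)
  hit <- atomResKeys(a) == key
  if (!any(hit)) return(NULL)
  a[hit, , drop = FALSE]
}

#' Minimum inter-residue atom distance
#'
#' @param a,b atom data.frames of two residues (as returned by
#'   \code{selectResidues}).
#' @param atoms \code{"heavy"} (default, excludes hydrogens), \code{"all"},
#'   or a character vector of atom names.
#' @return minimum Euclidean distance in Angstrom over all atom pairs
#'   passing the filter.
#' @export
minResidueDistance <- function(a, b, atoms = "heavy") {
  filt <- function(d) {
    if (identical(atoms, "heavy")) d[d$element != "H", , drop = FALSE]
    else if (identical(atoms, "all")) d
    else d[d$elety %in% atoms, , drop = FALSE]
  }
  fa <- filt(a); fb <- filt(b)
  if (nrow(fa) == 0 || nrow(fb) == 0)
    stop("no atoms pass the filter in one of the residues")
  A <- as.matrix(fa[, c("x", "y", "z")])
  B <- as.matrix(fb[, c("x", "y", "z")])
  sqrt(min(crossDist2(A, B)))
}

#' Heavy-atom centroid of a structure
#'
#' The rotation centre used by \code{\link{applyPose}} and by docking:
#' poses rotate the ligand about this point, so the transformed ligand
#' centroid is \code{ligandCenter(ligand) + t}.
#'
#' @param s \linkS4class{Structure}.
#' @export
ligandCenter <- function(s) {
  h <- heavyAtoms(s)
  if (nrow(h) == 0) stop("structure has no heavy atoms")
  colMeans(as.matrix(h[, c("x", "y", "z")]))
}

#' Apply a rigid pose to a structure
#'
#' Coordinates map as \code{x' = R (x - c) + c + t} where \code{c} is the
#' rotation centre (by default the heavy-atom centroid of \code{s}) --
#' rigid, so all internal distances are preserved.
#'
#' @param s ligand \linkS4class{Structure} in its reference placement.
#' @param poses \linkS4class{PoseSet}.
#' @param i which pose to apply (default 1).
#' @param center rotation centre; pass the reference ligand's centroid when
#'   transforming a sub-selection.
#' @return transformed \linkS4class{Structure}.
#' @export
applyPose <- function(s, poses, i = 1L, center = ligandCenter(s)) {
  stopifnot(i >= 1L, i <= length(poses))
  R <- quatToMatrix(poses@q[i, ])
  tr <- poses@t[i, ]
  a <- atomData(s)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2L, center) %*% t(R)
  xyz <- sweep(xyz, 2L, center + tr, "+")
  a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
  Structure(a, id = s@id, metadata = s@metadata)
}

#' Merge two structures into one (e.g. receptor + posed ligand)
#'
#' Chains must not collide.
#'
#' @param a,b \linkS4class{Structure}s.
#' @param id label for the merged structure.
#' @export
mergeStructures <- function(a, b, id = "complex") {
  if (length(intersect(chainIds(a), chainIds(b))) > 0)
    stop("chain identifiers collide between the two structures")
  Structure(rbind(atomData(a), atomData(b)), id = id)
}
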