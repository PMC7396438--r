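## Model-quality checks: backbone dihedrals with Ramachandran
## classification, sphere-point accessible surface area, and a 3D-1D
## environment-profile verify score with length-calibrated expected
## high/low bounds (expected low = 45% of expected high).

#' Backbone dihedral angles
#'
#' Standard phi (C[i-1], N, CA, C) and psi (N, CA, C, N[i+1]) torsions per
#' residue, right-handed sign convention, degrees in (-180, 180].
#' Chain-terminal residues have the corresponding angle undefined; a
#' missing backbone atom or degenerate (collinear) geometry yields an
#' undefined angle with a reason, not an error.
#'
#' @param s \linkS4class{Structure}.
#' @return data.frame(key, chain, resno, resid, phi, psi, reason).
#' @export
backboneDihedrals <- function(s) {
  a <- atomData(s)
  out <- list()
  for (ch in unique(a$chain)) {
    ca <- a[a$chain == ch, , drop = FALSE]
    keys <- unique(atomResKeys(ca))
    nres <- length(keys)
    getAtom <- function(ri, name) {
      res <- ca[atomResKeys(ca) == keys[ri], , drop = FALSE]
      row <- res[res$elety == name, , drop = FALSE]
      if (nrow(row) == 0) return(NULL)
      as.numeric(row[1L, c("x", "y", "z")])
    }
    phi <- psi <- rep(NA_real_, nres)
    reason <- character(nres)
    for (i in seq_len(nres)) {
      N <- getAtom(i, "N"); CA <- getAtom(i, "CA"); C <- getAtom(i, "C")
      if (is.null(N) || is.null(CA) || is.null(C)) {
        reason[i] <- "missing backbone atom"
        next
      }
      rs <- character(0)
      if (i > 1L) {
        Cprev <- getAtom(i - 1L, "C")
        if (is.null(Cprev)) rs <- c(rs, "missing C in preceding residue")
        else {
          phi[i] <- torsionAngle(Cprev, N, CA, C)
          if (is.na(phi[i])) rs <- c(rs, "degenerate phi geometry")
        }
      } else rs <- c(rs, "chain start: phi undefined")
      if (i < nres) {
        Nnext <- getAtom(i + 1L, "N")
        if (is.null(Nnext)) rs <- c(rs, "missing N in following residue")
        else {
          psi[i] <- torsionAngle(N, CA, C, Nnext)
          if (is.na(psi[i])) rs <- c(rs, "degenerate psi geometry")
        }
      } else rs <- c(rs, "chain end: psi undefined")
      reason[i] <- paste(rs, collapse = "; ")
    }
    first <- !duplicated(atomResKeys(ca))
    out[[ch]] <- data.frame(
      key = keys, chain = ch, resno = ca$resno[first],
      resid = ca$resid[first], phi = phi, psi = psi, reason = reason,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Favorable-region polygons for Ramachandran classification
#'
#' A two-level (favored + allowed combined) region set over (phi, psi):
#' the alpha basin, the beta/extended basin (continued across the psi =
#' 180 wrap) and the left-handed alpha basin, shipped as package data
#' (\code{inst/extdata/rama_regions.tsv}: region, phi, psi vertex rows).
#'
#' @param path optional path to a region polygon file.
#' @return data.frame(region, phi, psi) of polygon vertices.
#' @export
ramaRegions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rama_regions.tsv",
                        package = "xlinkdock")
  reg <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("region", "phi", "psi")
  if (!all(need %in% names(reg)) || nrow(reg) < 3)
    stop("malformed Ramachandran region file: ", path)
  reg
}

#' Classify dihedral records as favorable/unfavorable
#'
#' Point-in-polygon membership against the favorable regions, with
#' wrap-around: each point is also tested shifted by +-360 degrees in phi
#' and psi, so regions may extend past the nominal (-180, 180] range.
#' Residues with an undefined angle are classified \code{"undefined"}.
#'
#' @param records output of \code{\link{backboneDihedrals}}.
#' @param regions region polygons (default \code{\link{ramaRegions}()}).
#' @return records with a \code{classification} column; counts are in
#'   attribute \code{"counts"}.
#' @export
ramachandranClassify <- function(records, regions = ramaRegions()) {
  polys <- split(regions, regions$region)
  shifts <- c(-360, 0, 360)
  classify <- function(phi, psi) {
    if (is.na(phi) || is.na(psi)) return("undefined")
    for (poly in polys) {
      for (sp in shifts) for (ss in shifts) {
        if (pracma::inpolygon(phi + sp, psi + ss, poly$phi, poly$psi,
                              boundary = TRUE))
          return("favorable")
      }
    }
    "unfavorable"
  }
  records$classification <- mapply(classify, records$phi, records$psi)
  attr(records, "counts") <- table(records$classification)
  records
}

#' Side-chain buried fraction by sphere-point accessible area
#'
#' Shrake-Rupley-style accessible surface: quasi-uniform points on each
#' atom's solvent-extended sphere are tested against all neighbouring
#' atoms; the accessible area is the exposed-point fraction times the
#' sphere area. The side-chain buried fraction of a residue is
#' \code{1 - accessible(in structure) / accessible(residue isolated)},
#' over side-chain atoms (all atoms except N, CA, C, O; CA is used for
#' residues without side-chain atoms).
#'
#' @param s \linkS4class{Structure}.
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points sphere points per atom (>= 92).
#' @param radii per-element radii (defaults from
#'   \code{\link{energyParams}}).
#' @return data.frame(key, resid, acc_complex, acc_isolated, buried).
#' @export
accessibleArea <- function(s, probe = 1.4, n_points = 92L,
                           radii = energyParams()$radii) {
  stopifnot(n_points >= 92L)
  a <- heavyAtoms(s)
  if (nrow(a) == 0) stop("structure has no heavy atoms")
  miss <- setdiff(unique(a$element), names(radii))
  if (length(miss) > 0)
    stop("no radius parameter for element(s): ", paste(miss, collapse = ", "))
  pts <- spherePoints(n_points)
  atomAccessible <- function(xyz, rad) {
    n <- nrow(xyz)
    R <- rad + probe
    acc <- numeric(n)
    for (i in seq_len(n)) {
      sp <- sweep(pts * R[i], 2L, xyz[i, ], "+")
      nb <- which(rowSums(sweep(xyz, 2L, xyz[i, ])^2) <=
                    (R[i] + max(R))^2)
      nb <- setdiff(nb, i)
      exposed <- rep(TRUE, n_points)
      for (j in nb) {
        d2 <- rowSums(sweep(sp, 2L, xyz[j, ])^2)
        exposed <- exposed & d2 > R[j]^2
        if (!any(exposed)) break
      }
      acc[i] <- 4 * pi * R[i]^2 * mean(exposed)
    }
    acc
  }
  keys <- atomResKeys(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- unname(radii[a$element])
  accAll <- atomAccessible(xyz, rad)
  ukeys <- unique(keys)
  out <- data.frame(key = ukeys,
                    resid = a$resid[!duplicated(keys)],
                    acc_complex = NA_real_, acc_isolated = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in seq_along(ukeys)) {
    sel <- keys == ukeys[r]
    side <- sel & !(a$elety %in% c("N", "CA", "C", "O", "OXT"))
    if (!any(side)) side <- sel & a$elety == "CA"
    if (!any(side)) side <- sel
    accIso <- atomAccessible(xyz[sel, , drop = FALSE], rad[sel])
    names(accIso) <- which(sel)
    out$acc_complex[r] <- sum(accAll[side])
    out$acc_isolated[r] <- sum(accIso[as.character(which(side))])
  }
  out$buried <- ifelse(out$acc_isolated > 0,
                       pmax(0, 1 - out$acc_complex / out$acc_isolated), 0)
  out
}

#' 3D-1D environment score table
#'
#' Scores each amino-acid type in each of 18 environment classes (six
#' burial/polarity classes x three secondary-structure classes). The
#' shipped table (\code{inst/extdata/profile3d_scores_synthetic.tsv}) is a
#' synthetic calibration derived from hydropathy/burial compatibility --
#' suitable for grading relative model quality, not a reproduction of any
#' published profile table -- and can be replaced via \code{path}.
#'
#' @param path optional path to a 20 x 18 score table (TSV, row names =
#'   3-letter residue codes, column names = environment classes).
#' @export
profileScoreTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "profile3d_scores_synthetic.tsv",
                        package = "xlinkdock")
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              row.names = 1L, check.names = FALSE))
}

ENV_BURIAL <- c("E", "P1", "P2", "B1", "B2", "B3")
ENV_SS <- c("helix", "sheet", "other")

## burial/polarity -> one of the six environment classes
burialPolarityClass <- function(buried, polarFrac) {
  if (buried < 0.4) "E"
  else if (buried < 0.7) { if (polarFrac < 0.5) "P1" else "P2" }
  else { if (polarFrac < 1 / 3) "B1" else if (polarFrac < 2 / 3) "B2" else "B3" }
}

## secondary-structure class from (phi, psi) bins
ssClass <- function(phi, psi) {
  if (is.na(phi) || is.na(psi)) return("other")
  if (phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5) return("helix")
  if (phi >= -180 && phi <= -40 && (psi >= 60 || psi <= -150)) return("sheet")
  "other"
}

## fraction of polar atoms among other residues' heavy atoms within
## `shell` Angstrom of the residue's side-chain atoms
polarContactFraction <- function(s, shell = 4.5) {
  a <- heavyAtoms(s)
  keys <- atomResKeys(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  polar <- a$element %in% c("N", "O", "S")
  vapply(unique(keys), function(k) {
    sel <- keys == k
    side <- sel & !(a$elety %in% c("N", "CA", "C", "O", "OXT"))
    if (!any(side)) side <- sel & a$elety == "CA"
    D2 <- crossDist2(xyz[side, , drop = FALSE], xyz[!sel, , drop = FALSE])
    nb <- apply(D2 <= shell^2, 2L, any)
    if (!any(nb)) 0 else mean(polar[!sel][nb])
  }, numeric(1L))
}

#' Expected verify-score bounds
#'
#' The expected high score of a correct structure is calibrated on
#' residue count (default 0.45 per residue, configurable); the expected
#' low score is always 45 percent of the expected high score. Either
#' supply \code{nResidues} or fix \code{expectedHigh} directly.
#'
#' @param nResidues residue count.
#' @param expectedHigh override for the expected high score.
#' @param perResidue calibration constant (score units per residue).
#' @return named numeric c(high, low).
#' @export
expectedScoreBounds <- function(nResidues = NULL, expectedHigh = NULL,
                                perResidue = 0.45) {
  if (is.null(expectedHigh)) {
    stopifnot(!is.null(nResidues))
    expectedHigh <- perResidue * nResidues
  }
  c(high = expectedHigh, low = 0.45 * expectedHigh)
}

#' 3D-1D profile verification of a model
#'
#' Each residue is assigned an environment class from its side-chain
#' burial, polar-contact fraction and secondary structure, then scored
#' against the 20 x 18 profile table; the verify score is the sum of the
#' per-residue scores, compared against the length-calibrated expected
#' high score and the expected low score (45 percent of the high).
#'
#' @param s \linkS4class{Structure}.
#' @param table profile score table (see \code{\link{profileScoreTable}}).
#' @param probe,n_points accessible-area parameters.
#' @param perResidue expected-high calibration constant.
#' @return A \linkS4class{VerifyProfile}.
#' @export
verifyScore <- function(s, table = profileScoreTable(), probe = 1.4,
                        n_points = 92L, perResidue = 0.45) {
  if (nrow(atomData(s)) == 0 || nResidues(s) == 0) {
    return(new("VerifyProfile",
               residues = data.frame(key = character(), resid = character(),
                                     burial = numeric(), polarity = numeric(),
                                     ss = character(), envClass = character(),
                                     score = numeric()),
               verifyScore = 0, expectedHigh = 0, expectedLow = 0))
  }
  acc <- accessibleArea(s, probe, n_points)
  pol <- polarContactFraction(s)
  dih <- backboneDihedrals(s)
  dih <- dih[match(acc$key, dih$key), ]
  miss <- setdiff(unique(acc$resid), rownames(table))
  if (length(miss) > 0)
    stop("residue type(s) absent from the profile score table: ",
         paste(miss, collapse = ", "))
  env <- character(nrow(acc))
  score <- numeric(nrow(acc))
  for (i in seq_len(nrow(acc))) {
    bp <- burialPolarityClass(acc$buried[i], pol[[acc$key[i]]])
    sc <- ssClass(dih$phi[i], dih$psi[i])
    env[i] <- paste(bp, sc, sep = ".")
    score[i] <- table[acc$resid[i], env[i]]
  }
  bounds <- expectedScoreBounds(nResidues = nrow(acc),
                                perResidue = perResidue)
  new("VerifyProfile",
      residues = data.frame(key = acc$key, resid = acc$resid,
                            burial = acc$buried,
                            polarity = unname(pol[acc$key]),
                            ss = vapply(seq_len(nrow(acc)), function(i)
                              ssClass(dih$phi[i], dih$psi[i]), ""),
                            envClass = env, score = score,
                            stringsAsFactors = FALSE),
      verifyScore = sum(score),
      expectedHigh = unname(bounds["high"]),
      expectedLow = unname(bounds["low"]))
}

#' Grade a verify profile
#'
#' Three explicit bands: at or above the expected high score
#' (\code{"mostly_correct"}), between the expected low (inclusive) and
#' high scores (\code{"intermediate"}), and below the expected low score
#' (\code{"grossly_misfolded"}). Both of the upper bands indicate an
#' acceptably built model (\code{acceptable = TRUE}); only the bottom
#' band flags gross misfolding.
#'
#' @param profile \linkS4class{VerifyProfile}, or a list with elements
#'   verifyScore, expectedHigh, expectedLow.
#' @return list(label, acceptable, verifyScore, expectedHigh,
#'   expectedLow).
#' @export
classifyOutcome <- function(profile) {
  v <- if (is(profile, "VerifyProfile")) profile@verifyScore
       else profile$verifyScore
  hi <- if (is(profile, "VerifyProfile")) profile@expectedHigh
        else profile$expectedHigh
  lo <- if (is(profile, "VerifyProfile")) profile@expectedLow
        else profile$expectedLow
  label <- if (v >= hi) "mostly_correct"
           else if (v >= lo) "intermediate"
           else "grossly_misfolded"
  list(label = label, acceptable = label != "grossly_misfolded",
       verifyScore = v, expectedHigh = hi, expectedLow = lo)
}
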