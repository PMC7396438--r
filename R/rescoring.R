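## Detailed-energy rescoring of docked poses: split Lennard-Jones,
## screened Coulomb on residue-typed formal charges, and a pairwise
## contact desolvation term, combined as a weighted sum (lower is
## better). Used ordinally, to re-rank filtered poses.

#' Energy parameters for rescoring
#'
#' All tables are overridable. Van der Waals radii are per element;
#' pair well depth \code{epsilon} is uniform. Electrostatics use formal
#' charges (+1 on the lysine NZ and arginine CZ, -1 on the aspartate CG
#' and glutamate CD carboxylate midpoints) with a distance-dependent
#' dielectric \code{eps(r) = dielectric * r}. Desolvation is a pairwise
#' contact score over polar/apolar atom classes with a linear switch to
#' zero at the cutoff. Pair distances are floored at
#' \code{r_floor_frac * rmin} so clashing decoys stay finite.
#'
#' @param radii named van der Waals radii (Angstrom) per element.
#' @param epsilon LJ well depth.
#' @param cutoff pair cutoff, Angstrom (default 9).
#' @param coulomb Coulomb constant (kcal mol-1 A e-2).
#' @param dielectric slope of the distance-dependent dielectric.
#' @param desolv 2x2 matrix of contact weights over classes
#'   (polar, apolar).
#' @param r_floor_frac fraction of rmin used as the minimum pair distance.
#' @export
energyParams <- function(radii = c(C = 1.7, N = 1.55, O = 1.52, S = 1.8,
                                   P = 1.8, H = 1.2),
                         epsilon = 0.1, cutoff = 9, coulomb = 332,
                         dielectric = 4,
                         desolv = matrix(c(0, 0.5, 0.5, -0.5), 2L, 2L,
                           dimnames = list(c("polar", "apolar"),
                                           c("polar", "apolar"))),
                         r_floor_frac = 0.5) {
  list(radii = radii, epsilon = epsilon, cutoff = cutoff,
       coulomb = coulomb, dielectric = dielectric, desolv = desolv,
       r_floor_frac = r_floor_frac)
}

## formal charges by residue type and side-chain terminal atom
assignCharges <- function(atoms) {
  q <- numeric(nrow(atoms))
  q[atoms$resid == "LYS" & atoms$elety == "NZ"] <- 1
  q[atoms$resid == "ARG" & atoms$elety == "CZ"] <- 1
  q[atoms$resid == "ASP" & atoms$elety == "CG"] <- -1
  q[atoms$resid == "GLU" & atoms$elety == "CD"] <- -1
  q
}

#' Interaction energy terms between receptor and posed ligand
#'
#' Pairwise heavy-atom sums within the cutoff. The Lennard-Jones 6-12
#' potential is split with the shifted convention: for separations beyond
#' the combined radius the attractive part is the full LJ value and the
#' repulsive part is zero; inside it, the attractive part is held at the
#' well minimum (-epsilon) and the repulsive part is the excess above it
#' -- so \code{vdw_repulsive >= 0} always, and at exactly the combined
#' radius the repulsion is zero with the attraction at its minimum.
#'
#' @param receptor,ligand_posed \linkS4class{Structure}s.
#' @param params see \code{\link{energyParams}}.
#' @return named numeric: vdw_attractive, vdw_repulsive, elec_attractive,
#'   elec_repulsive, desolvation. All zero when the bodies are farther
#'   apart than the cutoff.
#' @export
energyTerms <- function(receptor, ligand_posed, params = energyParams()) {
  ra <- heavyAtoms(receptor)
  la <- heavyAtoms(ligand_posed)
  if (nrow(ra) == 0 || nrow(la) == 0)
    stop("both structures must contain heavy atoms")
  lookupRadius <- function(el) {
    miss <- setdiff(unique(el), names(params$radii))
    if (length(miss) > 0)
      stop("no van der Waals radius parameter for element(s): ",
           paste(miss, collapse = ", "))
    unname(params$radii[el])
  }
  rrad <- lookupRadius(ra$element)
  lrad <- lookupRadius(la$element)
  rq <- assignCharges(ra)
  lq <- assignCharges(la)
  rpol <- ifelse(ra$element %in% c("N", "O", "S"), "polar", "apolar")
  lpol <- ifelse(la$element %in% c("N", "O", "S"), "polar", "apolar")
  D2 <- crossDist2(as.matrix(ra[, c("x", "y", "z")]),
                   as.matrix(la[, c("x", "y", "z")]))
  hit <- which(D2 <= params$cutoff^2, arr.ind = TRUE)
  terms <- c(vdw_attractive = 0, vdw_repulsive = 0, elec_attractive = 0,
             elec_repulsive = 0, desolvation = 0)
  if (nrow(hit) == 0) return(terms)
  i <- hit[, 1L]; j <- hit[, 2L]
  r <- sqrt(D2[hit])
  rmin <- rrad[i] + lrad[j]
  r <- pmax(r, params$r_floor_frac * rmin)
  s6 <- (rmin / r)^6
  lj <- params$epsilon * (s6^2 - 2 * s6)
  inside <- r < rmin
  attr_ <- ifelse(inside, -params$epsilon, lj)
  rep_ <- ifelse(inside, lj + params$epsilon, 0)
  qq <- rq[i] * lq[j]
  elec <- params$coulomb * qq / (params$dielectric * r^2)
  dw <- params$desolv[cbind(rpol[i], lpol[j])]
  terms["vdw_attractive"] <- sum(attr_)
  terms["vdw_repulsive"] <- sum(rep_)
  terms["elec_attractive"] <- sum(elec[qq < 0])
  terms["elec_repulsive"] <- sum(elec[qq > 0])
  terms["desolvation"] <- sum(dw * (1 - r / params$cutoff))
  terms
}

#' Default rescoring weights
#'
#' One weight per energy term; the rescore is the weighted sum (lower is
#' better). The weights are configuration, not a fitted potential.
#'
#' @export
rescoreWeights <- function() {
  c(vdw_attractive = 1, vdw_repulsive = 0.5, elec_attractive = 1,
    elec_repulsive = 1, desolvation = 1)
}

#' Combine energy terms into a rescore
#'
#' @param terms named numeric from \code{\link{energyTerms}}.
#' @param weights named numeric weights.
#' @return scalar; lower is better.
#' @export
rescorePose <- function(terms, weights = rescoreWeights()) {
  sum(weights[names(terms)] * terms)
}

#' Select final models by the triple criterion
#'
#' Models with a high density, a high primary score and a low rescore are
#' preferred: records on the Pareto front of (density up, score up,
#' rescore down) rank before dominated ones, then a lexicographic order
#' (density desc, score desc, rescore asc, id asc) decides, and the top
#' k are returned.
#'
#' @param records annotated pose table carrying density, score and
#'   rescore columns.
#' @param k number of models (> 0); if larger than the record count, all
#'   records are returned in the stable order.
#' @export
selectModels <- function(records, k) {
  if (k <= 0) stop("k must be positive")
  n <- nrow(records)
  if (n == 0) return(records)
  dens <- records$density
  sc <- records$score
  rs <- records$rescore
  rs[is.na(rs)] <- 0
  dominated <- vapply(seq_len(n), function(i) {
    any(dens >= dens[i] & sc >= sc[i] & rs <= rs[i] &
        (dens > dens[i] | sc > sc[i] | rs < rs[i]))
  }, logical(1L))
  ord <- order(dominated, -dens, -sc, rs, records$id)
  records[ord, , drop = FALSE][seq_len(min(k, n)), , drop = FALSE]
}
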