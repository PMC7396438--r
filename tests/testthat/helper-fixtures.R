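## Shared fixture builders and independent brute-force oracles.

## one residue as an atom data.frame
mkResidue <- function(chain, resno, resid, elety, xyz) {
  xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
  data.frame(chain = chain, resno = as.integer(resno), insert = "",
             resid = resid, elety = elety,
             element = xlinkdock:::guessElement(elety),
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             stringsAsFactors = FALSE)
}

## random toy structure: nres residues of 3 atoms in a box of given side
mkRandomStructure <- function(nres, side = 15, chain = "A", seed = 1L,
                              id = "toy") {
  withr::with_seed(seed, {
    atoms <- do.call(rbind, lapply(seq_len(nres), function(i) {
      ctr <- stats::runif(3L, 0, side)
      mkResidue(chain, i, "ALA", c("N", "CA", "CB"),
                t(ctr + t(matrix(stats::rnorm(9L, 0, 0.8), 3L))))
    }))
  })
  Structure(atoms, id = id)
}

## occupancy grid with random cells, labelled surface/core
mkRandomGrid <- function(dims, p = 0.3, seed = 1L, spacing = 1.2) {
  withr::with_seed(seed, {
    occ <- array(as.integer(stats::runif(prod(dims)) < p), dims)
  })
  new("DockGrid", origin = c(0, 0, 0), spacing = spacing,
      dims = as.integer(dims), cells = xlinkdock:::labelSurfaceCore(occ))
}

## direct (non-spectral) correlation oracle: accumulate the receptor
## weight array over every occupied ligand cell offset
directCorrelate <- function(rec, lig, clash = 9) {
  dr <- rec@dims; dl <- lig@dims
  P <- dr + dl - 1L
  w <- array(0, dr)
  w[rec@cells == 1L] <- 1
  w[rec@cells == 2L] <- -clash
  out <- array(0, P)
  occ <- which(lig@cells > 0L, arr.ind = TRUE)
  shifts <- lapply(1:3, function(k) seq.int(-(dl[k] - 1L), dr[k] - 1L))
  for (r in seq_len(nrow(occ))) {
    j <- occ[r, ]
    ## score(t) += w[j + t] for t such that j + t is inside the receptor
    idx <- lapply(1:3, function(k) {
      t_ok <- shifts[[k]] + j[k]
      which(t_ok >= 1L & t_ok <= dr[k])
    })
    out[idx[[1]], idx[[2]], idx[[3]]] <-
      out[idx[[1]], idx[[2]], idx[[3]]] +
      w[j[1L] + shifts[[1]][idx[[1]]],
        j[2L] + shifts[[2]][idx[[2]]],
        j[3L] + shifts[[3]][idx[[3]]], drop = FALSE]
  }
  out
}

## fully naive per-translation triple loop (small grids only)
naiveCorrelate <- function(rec, lig, clash = 9) {
  dr <- rec@dims; dl <- lig@dims
  w <- array(0, dr)
  w[rec@cells == 1L] <- 1
  w[rec@cells == 2L] <- -clash
  L <- lig@cells > 0L
  P <- dr + dl - 1L
  out <- array(0, P)
  for (i1 in seq_len(P[1])) for (i2 in seq_len(P[2])) for (i3 in seq_len(P[3])) {
    t <- c(i1, i2, i3) - dl
    s <- 0
    for (j1 in seq_len(dl[1])) for (j2 in seq_len(dl[2])) for (j3 in seq_len(dl[3])) {
      if (!L[j1, j2, j3]) next
      r <- c(j1, j2, j3) + t
      if (all(r >= 1L) && all(r <= dr)) s <- s + w[r[1], r[2], r[3]]
    }
    out[i1, i2, i3] <- s
  }
  out
}

## brute-force interface oracle over all residue pairs
bruteInterface <- function(receptor, ligand, cutoff) {
  ra <- xlinkdock:::heavyAtoms(receptor)
  la <- xlinkdock:::heavyAtoms(ligand)
  rk <- unique(xlinkdock:::atomResKeys(ra))
  lk <- unique(xlinkdock:::atomResKeys(la))
  pairs <- NULL
  for (r in rk) for (l in lk) {
    d <- minResidueDistance(
      ra[xlinkdock:::atomResKeys(ra) == r, , drop = FALSE],
      la[xlinkdock:::atomResKeys(la) == l, , drop = FALSE])
    if (d <= cutoff)
      pairs <- rbind(pairs, data.frame(receptor = r, ligand = l, dist = d))
  }
  pairs
}

## brute-force density oracle
bruteDensity <- function(poses, ligand, radius) {
  ctr <- ligandCenter(ligand)
  cen <- sweep(poseTranslations(poses), 2L, ctr, "+")
  n <- nrow(cen)
  vapply(seq_len(n), function(i)
    sum(sqrt(colSums((t(cen) - cen[i, ])^2)) <= radius), 0L)
}

## annotated pose records for a decoy mixture around a synthetic system
mkAnnotatedDecoys <- function(sys, poses, ...) {
  annotatePoses(sys@receptor, sys@ligand, poses,
                restraints = sys@restraints, ...)
}
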