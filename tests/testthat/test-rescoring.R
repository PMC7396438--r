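oneAtom <- function(chain, resid, elety, xyz) {
  Structure(mkResidue(chain, 1, resid, elety, xyz), id = chain)
}

## independent per-pair reimplementation of the energy model
naiveEnergy <- function(receptor, ligand, params = energyParams()) {
  ra <- xlinkdock:::heavyAtoms(receptor)
  la <- xlinkdock:::heavyAtoms(ligand)
  qr <- xlinkdock:::assignCharges(ra)
  ql <- xlinkdock:::assignCharges(la)
  terms <- c(vdw_attractive = 0, vdw_repulsive = 0, elec_attractive = 0,
             elec_repulsive = 0, desolvation = 0)
  for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(la))) {
    r <- sqrt(sum((as.numeric(ra[i, c("x", "y", "z")]) -
                   as.numeric(la[j, c("x", "y", "z")]))^2))
    if (r > params$cutoff) next
    rmin <- params$radii[[ra$element[i]]] + params$radii[[la$element[j]]]
    r <- max(r, params$r_floor_frac * rmin)
    s6 <- (rmin / r)^6
    lj <- params$epsilon * (s6^2 - 2 * s6)
    if (r < rmin) {
      terms["vdw_attractive"] <- terms["vdw_attractive"] - params$epsilon
      terms["vdw_repulsive"] <- terms["vdw_repulsive"] + lj + params$epsilon
    } else terms["vdw_attractive"] <- terms["vdw_attractive"] + lj
    qq <- qr[i] * ql[j]
    if (qq != 0) {
      e <- params$coulomb * qq / (params$dielectric * r^2)
      if (qq < 0) terms["elec_attractive"] <- terms["elec_attractive"] + e
      else terms["elec_repulsive"] <- terms["elec_repulsive"] + e
    }
    pi_ <- if (ra$element[i] %in% c("N", "O", "S")) "polar" else "apolar"
    pj <- if (la$element[j] %in% c("N", "O", "S")) "polar" else "apolar"
    terms["desolvation"] <- terms["desolvation"] +
      params$desolv[pi_, pj] * (1 - r / params$cutoff)
  }
  terms
}

test_that("non-contacting bodies have identically zero energy terms", {
  a <- oneAtom("A", "ALA", "CA", c(0, 0, 0))
  b <- oneAtom("S", "ALA", "CA", c(20, 0, 0))
  expect_equal(energyTerms(a, b), c(vdw_attractive = 0, vdw_repulsive = 0,
                                    elec_attractive = 0, elec_repulsive = 0,
                                    desolvation = 0))
})

test_that("the LJ split hits its minimum at the combined radius", {
  p <- energyParams()
  rmin <- 2 * p$radii[["C"]]
  a <- oneAtom("A", "ALA", "CA", c(0, 0, 0))
  b <- oneAtom("S", "ALA", "CA", c(rmin, 0, 0))
  t <- energyTerms(a, b, p)
  expect_equal(unname(t["vdw_repulsive"]), 0)
  expect_equal(unname(t["vdw_attractive"]), -p$epsilon)
  ## inside the radius: repulsion positive, attraction held at the minimum
  b2 <- oneAtom("S", "ALA", "CA", c(0.8 * rmin, 0, 0))
  t2 <- energyTerms(a, b2, p)
  expect_gt(unname(t2["vdw_repulsive"]), 0)
  expect_equal(unname(t2["vdw_attractive"]), -p$epsilon)
})

test_that("energy terms match the naive per-pair oracle on toy poses", {
  sys <- makeBlockComplex(1, n_receptor = 60, n_ligand = 8,
                          interface_size = 4)
  dec <- makeDecoys(sys, 3, rot_sigma = 10, trans_sigma = 3, seed = 4)
  for (i in 1:3) {
    posed <- applyPose(sys@ligand, dec, i)
    expect_equal(energyTerms(sys@receptor, posed),
                 naiveEnergy(sys@receptor, posed), tolerance = 1e-9)
  }
})

test_that("charged pairs split into attractive and repulsive electrostatics", {
  k1 <- oneAtom("A", "LYS", "NZ", c(0, 0, 0))
  k2 <- oneAtom("S", "LYS", "NZ", c(4, 0, 0))
  t <- energyTerms(k1, k2)
  expect_gt(unname(t["elec_repulsive"]), 0)
  expect_equal(unname(t["elec_attractive"]), 0)
  d <- oneAtom("S", "ASP", "CG", c(4, 0, 0))
  t2 <- energyTerms(k1, d)
  expect_lt(unname(t2["elec_attractive"]), 0)
  expect_equal(unname(t2["elec_repulsive"]), 0)
})

test_that("missing element parameters are a naming error", {
  a <- oneAtom("A", "ALA", "CA", c(0, 0, 0))
  fe <- Structure(data.frame(chain = "S", resno = 1L, insert = "",
                             resid = "ALA", elety = "FE", element = "FE",
                             x = 3, y = 0, z = 0))
  expect_error(energyTerms(a, fe), "FE")
})

test_that("the rescore is a weighted sum, lower for better-packed poses", {
  expect_equal(rescorePose(c(vdw_attractive = 0, vdw_repulsive = 0,
                             elec_attractive = 0, elec_repulsive = 0,
                             desolvation = 0)), 0)
  t <- c(vdw_attractive = -2, vdw_repulsive = 1, elec_attractive = -0.5,
         elec_repulsive = 0.2, desolvation = -0.1)
  w <- rescoreWeights()
  expect_equal(rescorePose(t, 2 * w), 2 * rescorePose(t, w))
  ## clash-heavy decoy scores worse (higher) than the native pose
  sys <- makeBlockComplex(1)
  natScore <- rescorePose(energyTerms(sys@receptor, sys@ligand))
  crash <- applyPose(sys@ligand, PoseSet(c(1, 0, 0, 0), c(0, 0, -3)))
  crashScore <- rescorePose(energyTerms(sys@receptor, crash))
  expect_gt(crashScore, natScore)
})

test_that("energy terms are invariant under a joint rigid transform", {
  sys <- makeBlockComplex(2, n_receptor = 60, n_ligand = 8,
                          interface_size = 4)
  t0 <- energyTerms(sys@receptor, sys@ligand)
  joint <- PoseSet(xlinkdock:::axisAngleToQuat(c(3, 1, -2), 61), c(-4, 7, 1))
  ctr <- ligandCenter(sys@ligand)
  t1 <- energyTerms(applyPose(sys@receptor, joint, center = ctr),
                    applyPose(sys@ligand, joint, center = ctr))
  expect_equal(t1, t0, tolerance = 1e-6)
})

test_that("model selection respects Pareto dominance and its tie order", {
  rec1 <- data.frame(id = 1L, density = 5L, score = 10, rescore = -1)
  expect_equal(selectModels(rec1, 3), rec1)
  expect_error(selectModels(rec1, 0), "positive")
  withr::with_seed(13, {
    for (trial in 1:5) {
      n <- 12
      recs <- data.frame(id = 1:n, density = sample(1:6, n, TRUE),
                         score = round(stats::runif(n, 0, 50)),
                         rescore = round(stats::rnorm(n), 2))
      sel <- selectModels(recs, n)     # k >= n: all records, stably ordered
      expect_setequal(sel$id, recs$id)
      ## a record dominated on all three axes never precedes its dominator
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        dominates <- recs$density[i] >= recs$density[j] &&
          recs$score[i] >= recs$score[j] &&
          recs$rescore[i] <= recs$rescore[j] &&
          (recs$density[i] > recs$density[j] ||
           recs$score[i] > recs$score[j] ||
           recs$rescore[i] < recs$rescore[j])
        if (dominates)
          expect_lt(match(recs$id[i], sel$id), match(recs$id[j], sel$id))
      }
      top <- selectModels(recs, 3)
      expect_equal(nrow(top), 3L)
      expect_equal(top$id, sel$id[1:3])
    }
  })
})
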