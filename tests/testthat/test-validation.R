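test_that("backbone dihedrals agree with an independent torsion oracle", {
  withr::with_seed(17, {
    for (k in 1:6) {
      p <- matrix(stats::rnorm(12, sd = 3), 4, 3)
      mine <- xlinkdock:::torsionAngle(p[1, ], p[2, ], p[3, ], p[4, ])
      ref <- bio3d::torsion.xyz(as.vector(t(p)))
      expect_equal(mine, as.numeric(ref), tolerance = 1e-6)
    }
  })
})

test_that("terminal, incomplete and degenerate residues are undefined with reasons", {
  one <- Structure(mkResidue("A", 1, "ALA", c("N", "CA", "C"),
                             c(0, 0, 0, 1.4, 0, 0, 2, 1, 0)))
  d <- backboneDihedrals(one)
  expect_true(is.na(d$phi) && is.na(d$psi))
  expect_match(d$reason, "chain start")
  expect_match(d$reason, "chain end")
  ## collinear backbone: dihedral undefined for degenerate geometry
  atoms <- rbind(
    mkResidue("A", 1, "ALA", c("N", "CA", "C"),
              c(0, 0, 0, 1, 0, 0, 2, 0, 0)),
    mkResidue("A", 2, "ALA", c("N", "CA", "C"),
              c(3, 0, 0, 4, 0, 0, 5, 1, 0)))
  d2 <- backboneDihedrals(Structure(atoms))
  expect_true(is.na(d2$phi[2]))
  expect_match(d2$reason[2], "degenerate phi")
  ## missing backbone atom
  atoms3 <- rbind(mkResidue("A", 1, "ALA", c("N", "CA"), c(0, 0, 0, 1, 0, 0)),
                  mkResidue("A", 2, "ALA", c("N", "CA", "C"),
                            c(2, 0, 0, 3, 1, 0, 4, 0, 0)))
  d3 <- backboneDihedrals(Structure(atoms3))
  expect_match(d3$reason[1], "missing backbone atom")
})

test_that("Ramachandran classification places canonical basins correctly", {
  rec <- data.frame(key = c("A:1", "A:2", "A:3", "A:4"),
                    phi = c(-57, 60, -120, NA),
                    psi = c(-47, -120, 140, 20))
  out <- ramachandranClassify(rec)
  expect_equal(out$classification,
               c("favorable", "unfavorable", "favorable", "undefined"))
  ## invariant to +-360 shifts
  rec2 <- rec; rec2$phi <- rec2$phi + 360; rec2$psi <- rec2$psi - 360
  expect_equal(ramachandranClassify(rec2)$classification,
               out$classification)
  ## wrap-around: an extended residue with psi near -180
  rec3 <- data.frame(key = "A:1", phi = -120, psi = -170)
  expect_equal(ramachandranClassify(rec3)$classification, "favorable")
  ## malformed region file
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("nope\tx", bad)
  expect_error(ramaRegions(bad), "malformed|undefined columns")
})

test_that("helix fixtures classify as favorable end to end", {
  d <- ramachandranClassify(backboneDihedrals(makeHelixBackbone(8)))
  interior <- d[!is.na(d$phi) & !is.na(d$psi), ]
  expect_true(all(interior$classification == "favorable"))
  counts <- attr(d, "counts")
  expect_equal(unname(counts["favorable"]), nrow(interior))
})

test_that("buried fractions behave at the exposed and enclosed extremes", {
  iso <- Structure(mkResidue("A", 1, "LYS", c("N", "CA", "C", "CB"),
                             c(-1.4, 0, 0, 0, 0, 0, 1.4, 0, 0, 0, 1.4, 0)))
  a <- accessibleArea(iso)
  expect_equal(a$buried, 0)
  ## residue enclosed in a dense synthetic cage
  pts <- xlinkdock:::spherePoints(80) * 4
  cage <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i)
    mkResidue("B", i + 1L, "ALA", "CA", pts[i, ])))
  caged <- Structure(rbind(atomData(iso)[, ], cage))
  a2 <- accessibleArea(caged)
  expect_gt(a2$buried[a2$key == "A:1"], 0.9)
  ## sphere-point convergence
  a92 <- accessibleArea(caged, n_points = 92)
  a184 <- accessibleArea(caged, n_points = 184)
  expect_true(all(abs(a92$buried - a184$buried) < 0.05))
})

test_that("expected score bounds keep the 45 percent relation at all lengths", {
  for (n in c(10, 100, 410, 1000)) {
    b <- expectedScoreBounds(nResidues = n)
    expect_equal(unname(b["low"] / b["high"]), 0.45)
  }
  b <- expectedScoreBounds(expectedHigh = 184.27)
  expect_equal(unname(b["low"]), 82.92, tolerance = 0.005)
})

test_that("verify scores sum per-residue scores and respect the bounds", {
  sys <- makeBlockComplex(1, n_receptor = 60, n_ligand = 8,
                          interface_size = 4)
  prof <- verifyScore(sys@ligand)
  expect_s4_class(prof, "VerifyProfile")
  expect_equal(prof@verifyScore, sum(prof@residues$score))
  expect_equal(prof@expectedLow, 0.45 * prof@expectedHigh)
  expect_equal(prof@expectedHigh, 0.45 * nResidues(sys@ligand))
  ## permuting residue order leaves the total unchanged
  a <- atomData(sys@ligand)
  perm <- unique(a$resno)[c(3, 1, 2, 6, 5, 4)]
  a2 <- a[order(match(a$resno, perm)), ]
  prof2 <- verifyScore(Structure(a2))
  expect_equal(prof2@verifyScore, prof@verifyScore, tolerance = 1e-9)
  ## empty structure scores zero
  empty <- Structure(atomData(sys@ligand)[0, ])
  expect_equal(verifyScore(empty)@verifyScore, 0)
})

test_that("verify score is additive over non-interacting fragments", {
  h1 <- makeHelixBackbone(6)
  a2 <- atomData(makeHelixBackbone(6))
  a2$chain <- "B"
  a2$x <- a2$x + 100
  h2 <- Structure(a2)
  merged <- mergeStructures(h1, h2)
  expect_equal(verifyScore(merged)@verifyScore,
               verifyScore(h1)@verifyScore + verifyScore(h2)@verifyScore,
               tolerance = 1e-6)
})

test_that("unknown residue types are a parameterization error", {
  odd <- Structure(data.frame(chain = "A", resno = 1L, insert = "",
                              resid = "XYZ", elety = c("N", "CA", "C", "CB"),
                              element = c("N", "C", "C", "C"),
                              x = c(-1.4, 0, 1.4, 0), y = c(0, 0, 0, 1.4),
                              z = 0))
  expect_error(verifyScore(odd), "XYZ")
})

test_that("outcome grading uses the three explicit bands", {
  out <- classifyOutcome(list(verifyScore = 167.31, expectedHigh = 184.27,
                              expectedLow = 82.92))
  expect_equal(out$label, "intermediate")
  expect_true(out$acceptable)
  expect_equal(classifyOutcome(list(verifyScore = 190, expectedHigh = 184.27,
                                    expectedLow = 82.92))$label,
               "mostly_correct")
  low <- classifyOutcome(list(verifyScore = 50, expectedHigh = 184.27,
                              expectedLow = 82.92))
  expect_equal(low$label, "grossly_misfolded")
  expect_false(low$acceptable)
  ## boundary: exactly at the expected low score joins the between band
  expect_equal(classifyOutcome(list(verifyScore = 82.92,
                                    expectedHigh = 184.27,
                                    expectedLow = 82.92))$label,
               "intermediate")
})
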