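test_that("a single atom occupies exactly one surface cell at coarse spacing", {
  s <- Structure(mkResidue("A", 1, "ALA", "CA", c(0, 0, 0)))
  g <- discretizeStructure(s, spacing = 5)
  expect_equal(sum(g@cells > 0L), 1L)
  expect_equal(sum(g@cells == 1L), 1L)
})

test_that("surface/core labelling matches the 6-neighbour definition", {
  solid <- array(1L, c(3, 3, 3))
  lab <- xlinkdock:::labelSurfaceCore(solid)
  expect_equal(sum(lab == 1L), 26L)
  expect_equal(sum(lab == 2L), 1L)
  expect_equal(lab[2, 2, 2], 2L)
})

test_that("blocked residues are cleared from the grid", {
  sys <- makeBlockComplex(1, n_receptor = 60, n_ligand = 8,
                          interface_size = 4)
  g <- discretizeStructure(sys@receptor, blocked = residueKeys(sys@receptor))
  expect_equal(sum(g@cells), 0L)
  gb <- discretizeStructure(sys@receptor, blocked = sys@blockedResidues)
  gf <- discretizeStructure(sys@receptor)
  expect_lt(sum(gb@cells > 0), sum(gf@cells > 0))
  expect_identical(gb@dims, gf@dims)   # extent unchanged by blocking
})

test_that("grid size above the cap is a resource error", {
  s <- Structure(mkResidue("A", 1, "ALA", c("CA", "CB"),
                           c(0, 0, 0, 60, 60, 60)))
  expect_error(discretizeStructure(s, spacing = 0.4, cap = 64L), "cap")
})

test_that("spectral correlation equals the naive double loop", {
  g1 <- mkRandomGrid(c(6, 5, 4), p = 0.4, seed = 2)
  g2 <- mkRandomGrid(c(3, 4, 3), p = 0.4, seed = 3)
  expect_lt(max(abs(correlateGrids(g1, g2, clash = 9) -
                    naiveCorrelate(g1, g2, clash = 9))), 1e-6)
})

test_that("spectral correlation matches the direct oracle on random grids", {
  for (seed in 1:3) {
    g1 <- mkRandomGrid(c(8, 8, 8), p = 0.35, seed = seed)
    g2 <- mkRandomGrid(c(8, 8, 8), p = 0.35, seed = seed + 10)
    expect_lt(max(abs(correlateGrids(g1, g2) - directCorrelate(g1, g2))),
              1e-6)
  }
})

test_that("degenerate correlation inputs behave as documented", {
  g1 <- mkRandomGrid(c(5, 5, 5), p = 0.4, seed = 1)
  empty <- new("DockGrid", origin = c(0, 0, 0), spacing = 1.2,
               dims = c(3L, 3L, 3L), cells = array(0L, c(3, 3, 3)))
  expect_true(all(correlateGrids(g1, empty) == 0))
  ## single surface receptor cell vs single ligand cell: +1 only at the
  ## aligning translation
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  gr <- new("DockGrid", origin = c(0, 0, 0), spacing = 1.2,
            dims = c(3L, 3L, 3L),
            cells = xlinkdock:::labelSurfaceCore(one))
  sc <- correlateGrids(gr, gr)
  expect_equal(sum(sc == 1), 1L)
  expect_true(all(sc %in% c(0, 1)))
  sh <- attr(sc, "shifts")
  hit <- which(sc == 1, arr.ind = TRUE)
  expect_equal(c(sh[[1]][hit[1]], sh[[2]][hit[2]], sh[[3]][hit[3]]),
               c(0L, 0L, 0L))
  ## spacing mismatch
  g3 <- mkRandomGrid(c(4, 4, 4), seed = 1, spacing = 1.5)
  expect_error(correlateGrids(g1, g3), "spacing")
})

test_that("a deeper clash penalty never favours clashing placements", {
  g1 <- mkRandomGrid(c(7, 6, 5), p = 0.5, seed = 5)
  g2 <- mkRandomGrid(c(4, 4, 4), p = 0.5, seed = 6)
  s1 <- correlateGrids(g1, g2, clash = 3)
  s2 <- correlateGrids(g1, g2, clash = 6)
  expect_true(all(s2 <= s1 + 1e-9))
  clashing <- abs(s2 - s1) > 1e-9
  expect_true(any(clashing))           # fixture does produce clashes
  expect_true(all(s2[clashing] < s1[clashing]))
})

test_that("docking recovers the planted native pose", {
  sys <- makeBlockComplex(1)
  rot <- rotationSet(8, seed = 1)    # contains the native rotation first
  poses <- dockSearch(sys@receptor, sys@ligand, rot,
                      blocked = sys@blockedResidues, top_n = 50)
  expect_s4_class(poses, "PoseSet")
  best <- poseTranslations(poses)[1, ]
  expect_lt(max(abs(best)), 1.2)     # within one grid cell of native
})

test_that("docking search is deterministic and validates its inputs", {
  sys <- makeBlockComplex(2, n_receptor = 60, n_ligand = 10,
                          interface_size = 4)
  rot <- rotationSet(5, seed = 3)
  p1 <- dockSearch(sys@receptor, sys@ligand, rot, top_n = 20)
  p2 <- dockSearch(sys@receptor, sys@ligand, rot, top_n = 20)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_error(dockSearch(sys@receptor, sys@ligand,
                          new("RotationSet", q = matrix(numeric(0), 0, 4),
                              scheme = "none", seed = 0L)),
               "empty rotation set")
  ## hydrogen-only ligand: empty pose list with a warning, not an error
  hlig <- Structure(mkResidue("S", 1, "ALA", c("H", "H"),
                              c(0, 0, 0, 1, 0, 0)))
  expect_warning(pe <- dockSearch(sys@receptor, hlig, rot, top_n = 1),
                 "no heavy atoms")
  expect_equal(length(pe), 0L)
})

test_that("jointly rotating receptor and ligand preserves the optimum", {
  ## grid origins re-snap to the rotated bounding box, so the optimum is
  ## preserved up to one cell of discretisation error, not bitwise
  sys <- makeBlockComplex(3, n_receptor = 60, n_ligand = 10,
                          interface_size = 4)
  rot <- rotationSet(1, seed = 1)    # identity only
  p0 <- dockSearch(sys@receptor, sys@ligand, rot, top_n = 5)
  ctr <- ligandCenter(sys@ligand)
  for (ang in c(90, 37)) {
    joint <- PoseSet(xlinkdock:::axisAngleToQuat(c(0, 0, 1), ang),
                     c(0, 0, 0))
    recR <- applyPose(sys@receptor, joint, center = ctr)
    ligR <- applyPose(sys@ligand, joint, center = ctr)
    pR <- dockSearch(recR, ligR, rot, top_n = 5)
    expect_gt(poseScores(pR)[1], 0.6 * poseScores(p0)[1])
    expect_lt(poseScores(pR)[1], 1.6 * poseScores(p0)[1])
    ## and the optimum stays at the pocket (small centroid displacement)
    expect_lt(sqrt(sum(poseTranslations(pR)[1, ]^2)), 3 * 1.2)
  }
})

test_that("rotation sets are unit-norm, seeded and contain the identity", {
  r1 <- rotationSet(20, seed = 7)
  r2 <- rotationSet(20, seed = 7)
  expect_identical(r1@q, r2@q)
  expect_equal(r1@q[1, ], c(qw = 1, qx = 0, qy = 0, qz = 0))
  expect_true(all(abs(sqrt(rowSums(r1@q^2)) - 1) < 1e-9))
  r3 <- rotationSet(20, seed = 8)
  expect_false(identical(r1@q, r3@q))
})

test_that("poses round-trip through their TSV form", {
  sys <- makeBlockComplex(1, n_receptor = 60, n_ligand = 8,
                          interface_size = 4)
  poses <- dockSearch(sys@receptor, sys@ligand, rotationSet(3, seed = 2),
                      top_n = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  writePoses(poses, f)
  p2 <- readPoses(f)
  expect_equal(as.data.frame(p2), as.data.frame(poses), tolerance = 1e-9)
})
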