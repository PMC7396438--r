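twoResidueStructures <- function(gap) {
  list(rec = Structure(mkResidue("A", 1, "ALA", "CA", c(0, 0, 0)), id = "r"),
       lig = Structure(mkResidue("S", 1, "ALA", "CA", c(gap, 0, 0)), id = "l"))
}

test_that("interface membership respects the cutoff exactly", {
  near <- twoResidueStructures(4.9)
  im <- interfaceResidues(near$rec, near$lig, cutoff = 5)
  expect_equal(im@receptorResidues, "A:1")
  expect_equal(im@ligandResidues, "S:1")
  far <- twoResidueStructures(5.1)
  im2 <- interfaceResidues(far$rec, far$lig, cutoff = 5)
  expect_length(im2@receptorResidues, 0)
  expect_equal(nrow(im2@contacts), 0L)
})

test_that("interface detection agrees with the exhaustive oracle", {
  rec <- mkRandomStructure(12, side = 14, chain = "A", seed = 5)
  lig <- mkRandomStructure(10, side = 14, chain = "S", seed = 6)
  im <- interfaceResidues(rec, lig, cutoff = 6)
  brute <- bruteInterface(rec, lig, 6)
  expect_equal(nrow(im@contacts), nrow(brute))
  ord <- order(brute$receptor, brute$ligand)
  expect_equal(im@contacts$receptor, brute$receptor[ord])
  expect_equal(im@contacts$ligand, brute$ligand[ord])
  expect_equal(im@contacts$dist, brute$dist[ord], tolerance = 1e-9)
  expect_true(all(im@contacts$dist <= 6))
  expect_setequal(im@receptorResidues, unique(brute$receptor))
})

test_that("leader clustering partitions poses by ligand position", {
  sys <- makeBlockComplex(1)
  same <- PoseSet(matrix(rep(c(1, 0, 0, 0), 3), ncol = 4, byrow = TRUE),
                  matrix(0, 3, 3), score = c(3, 2, 1))
  cl <- clusterPoses(same, sys@ligand, radius = 10)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$n, 3L)
  expect_equal(cl$clusters$representative, 1L)   # highest score
  two <- PoseSet(matrix(rep(c(1, 0, 0, 0), 2), ncol = 4, byrow = TRUE),
                 rbind(c(0, 0, 0), c(20, 0, 0)), score = c(1, 2))
  cl2 <- clusterPoses(two, sys@ligand, radius = 10)
  expect_equal(nrow(cl2$clusters), 2L)
  expect_equal(cl2$clusters$n, c(1L, 1L))
  ## every pose in exactly one cluster
  expect_setequal(cl2$assignments$id, poseIds(two))
})

test_that("two planted decoy sites are recovered as two clusters", {
  sys <- makeBlockComplex(1)
  a <- makeDecoys(sys, 25, rot_sigma = 0, trans_sigma = 1, seed = 1)
  b <- makeDecoys(sys, 25, rot_sigma = 0, trans_sigma = 1, seed = 2)
  bt <- poseTranslations(b); bt[, 1] <- bt[, 1] + 40
  poses <- PoseSet(rbind(poseQuaternions(a), poseQuaternions(b)),
                   rbind(poseTranslations(a), bt),
                   score = rep(0, 50), id = 1:50)
  cl <- clusterPoses(poses, sys@ligand, radius = 10)
  expect_equal(nrow(cl$clusters), 2L)
  grp <- cl$assignments$cluster
  expect_equal(length(unique(grp[1:25])), 1L)
  expect_equal(length(unique(grp[26:50])), 1L)
  expect_false(grp[1] == grp[26])
})

test_that("pose density counts neighbours inclusively and matches brute force", {
  sys <- makeBlockComplex(1)
  one <- identityPose()
  expect_equal(poseDensity(one, sys@ligand, 10), 1L)
  k <- PoseSet(matrix(rep(c(1, 0, 0, 0), 4), ncol = 4, byrow = TRUE),
               matrix(0, 4, 3))
  expect_equal(poseDensity(k, sys@ligand, 10), rep(4L, 4))
  dec <- makeDecoys(sys, 40, rot_sigma = 10, trans_sigma = 12, seed = 3)
  expect_equal(poseDensity(dec, sys@ligand, 8),
               bruteDensity(dec, sys@ligand, 8))
})

test_that("empty criteria pass everything; impossible criteria fail everything", {
  sys <- makeBlockComplex(1)
  dec <- makeDecoys(sys, 6, rot_sigma = 5, trans_sigma = 1, seed = 2)
  rec <- annotatePoses(sys@receptor, sys@ligand, dec)
  out <- filterPoses(rec, FilterCriteria())
  expect_true(all(out$passed))
  expect_true(all(lengths(out$fail_reasons) == 0))
  ## a required residue that is never in any interface: the blocked
  ## bottom layer sits >= 8 A from the native ligand placement
  lonely <- sys@blockedResidues[1]
  crit <- FilterCriteria(requiredReceptorInterface = lonely)
  out2 <- filterPoses(rec, crit)
  expect_false(any(out2$passed))
  expect_true(all(lengths(out2$fail_reasons) == 1))
  expect_true(all(grepl("required_receptor_interface", unlist(out2$fail_reasons))))
})

test_that("near-native poses pass ground-truth criteria and far decoys fail", {
  sys <- makeBlockComplex(1)
  crit <- syntheticCriteria(sys)
  near <- makeDecoys(sys, 5, rot_sigma = 0, trans_sigma = 0, seed = 1)
  far <- makeDecoys(sys, 10, rot_sigma = 30, trans_sigma = 50, seed = 2)
  poses <- PoseSet(rbind(poseQuaternions(near), poseQuaternions(far)),
                   rbind(poseTranslations(near), poseTranslations(far)),
                   score = rep(0, 15), id = 1:15)
  rec <- annotatePoses(sys@receptor, sys@ligand, poses)
  out <- filterPoses(rec, crit, sys@receptor, sys@ligand)
  expect_true(all(out$passed[1:5]))
  expect_false(any(out$passed[6:15]))
})

test_that("adding a required residue never enlarges the passing set", {
  sys <- makeBlockComplex(2)
  dec <- makeDecoys(sys, 25, rot_sigma = 15, trans_sigma = 8, seed = 5)
  rec <- annotatePoses(sys@receptor, sys@ligand, dec)
  keys <- residueKeys(sys@receptor)
  withr::with_seed(8, {
    for (trial in 1:6) {
      base <- sample(keys, sample(0:2, 1))
      extra <- sample(setdiff(keys, base), 1)
      p1 <- sum(filterPoses(rec, FilterCriteria(
        requiredReceptorInterface = base))$passed)
      p2 <- sum(filterPoses(rec, FilterCriteria(
        requiredReceptorInterface = c(base, extra)))$passed)
      expect_lte(p2, p1)
    }
  })
})

test_that("criteria referencing absent residues are a config error", {
  sys <- makeBlockComplex(1, n_receptor = 60, n_ligand = 8,
                          interface_size = 4)
  crit <- FilterCriteria(requiredReceptorInterface = "A:999")
  expect_error(validateCriteria(crit, sys@receptor, sys@ligand), "A:999")
  dec <- makeDecoys(sys, 2, seed = 1)
  rec <- annotatePoses(sys@receptor, sys@ligand, dec)
  expect_error(filterPoses(rec, crit, sys@receptor, sys@ligand), "A:999")
})

test_that("pose tables and score-density points export faithfully", {
  sys <- makeBlockComplex(1, n_receptor = 60, n_ligand = 8,
                          interface_size = 4)
  dec <- makeDecoys(sys, 4, rot_sigma = 5, trans_sigma = 2, seed = 7)
  rec <- annotatePoses(sys@receptor, sys@ligand, dec,
                       restraints = sys@restraints)
  rec <- filterPoses(rec, FilterCriteria())
  f <- withr::local_tempfile(fileext = ".tsv")
  exportPoseTable(rec, f)
  back <- readPoseTable(f)
  expect_equal(nrow(back), nrow(rec))
  for (col in c("id", "cluster", "density", "score", "sat_count"))
    expect_equal(back[[col]], rec[[col]])
  ## empty table: header only
  f2 <- withr::local_tempfile(fileext = ".tsv")
  exportPoseTable(rec[0, ], f2)
  expect_equal(length(readLines(f2)), 1L)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  exportScoreDensityPoints(rec, f3)
  pts <- utils::read.table(f3, header = TRUE, sep = "\t")
  expect_equal(names(pts), c("score", "density", "cluster"))
  expect_equal(nrow(pts), nrow(rec))
})

test_that("criteria round-trip through YAML", {
  crit <- FilterCriteria(requiredReceptorInterface = c("A:64", "A:135"),
                         requiredLigandDomain = c("S:1", "S:2"),
                         minDomainFraction = 0.6,
                         orientationRequired = "S:1",
                         orientationForbidden = "S:9",
                         blocked = c("B:1", "B:2"))
  f <- withr::local_tempfile(fileext = ".yaml")
  writeCriteria(crit, f)
  back <- readCriteria(f)
  expect_equal(back@requiredReceptorInterface,
               crit@requiredReceptorInterface)
  expect_equal(back@minDomainFraction, 0.6)
  expect_equal(back@orientationForbidden, "S:9")
  expect_equal(back@blocked, crit@blocked)
})
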