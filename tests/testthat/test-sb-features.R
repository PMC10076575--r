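test_that("best-pose features take rank-1 rows and average across isomers", {
  bp <- featureValues(bestPoseFeatures(handPoseTable()))
  expect_equal(bp["C1", "ENG.scoreA"], (-9 + -5) / 2)
  expect_equal(bp["C1", "ENG.scoreB"], (2 + 4) / 2)   # best of each isomer: 2 and 4 -> 3
})

test_that("average features are the pooled mean over all poses of all isomers", {
  av <- featureValues(averagePoseFeatures(handPoseTable()))
  expect_equal(av["C1", "ENG.scoreA"], mean(c(-9, -7, -5, -3)))
  expect_equal(av["C1", "ENG.scoreB"], mean(c(2, 1, 4, 5)))
})

test_that("a simple five-pose compound averages to the arithmetic mean", {
  rows <- data.frame(compound_id = "X", isomer_id = "X_i1", pose_rank = 1:5,
                     s = c(1, 2, 3, 4, 5))
  pt <- validatePoseTable(rows, engine = "E")
  expect_equal(featureValues(averagePoseFeatures(pt))["X", "E.s"], 3)
  expect_equal(featureValues(bestPoseFeatures(pt))["X", "E.s"], 1)
})

test_that("single-pose compounds pass through both aggregations unchanged", {
  rows <- data.frame(compound_id = c("A", "B"), isomer_id = c("A_i1", "B_i1"),
                     pose_rank = 1L, s1 = c(-3, 2), s2 = c(0.5, 1.5))
  pt <- validatePoseTable(rows, engine = "E")
  expect_equal(featureValues(bestPoseFeatures(pt)),
               featureValues(averagePoseFeatures(pt)))
  expect_equal(featureValues(bestPoseFeatures(pt))["A", "E.s1"], -3)
})

test_that("aggregated values stay within each compound's pose extrema", {
  co <- sharedCohort()
  pt <- co@poseTables[["PLANTS"]]
  sc <- poseScores(pt)
  av <- featureValues(averagePoseFeatures(pt))
  bp <- featureValues(bestPoseFeatures(pt))
  col <- scoreNames(pt)[3]
  lo <- tapply(sc[[col]], sc$compound_id, min)
  hi <- tapply(sc[[col]], sc$compound_id, max)
  ids <- rownames(av)
  expect_true(all(av[, paste0("PLANTS.", col)] >= lo[ids] - 1e-12))
  expect_true(all(av[, paste0("PLANTS.", col)] <= hi[ids] + 1e-12))
  expect_true(all(bp[ids, paste0("PLANTS.", col)] >= lo[ids] - 1e-12))
  expect_true(all(bp[ids, paste0("PLANTS.", col)] <= hi[ids] + 1e-12))
  # one row per docked compound, never more
  expect_equal(nrow(av), length(unique(sc$compound_id)))
})

test_that("pose-table validation catches duplicate keys and rank gaps", {
  dup <- data.frame(compound_id = "C", isomer_id = "C_i1", pose_rank = c(1L, 1L),
                    s = c(1, 2))
  expect_error(validatePoseTable(dup, engine = "E"), "duplicate.*C C_i1 1")
  gap <- data.frame(compound_id = "C", isomer_id = "C_i1", pose_rank = c(1L, 2L, 4L),
                    s = 1:3)
  expect_error(validatePoseTable(gap, engine = "E"), "not contiguous")
  clean <- poseScores(sharedCohort()@poseTables[["GOLD"]])
  expect_s4_class(validatePoseTable(clean, engine = "GOLD"), "PoseScoreTable")
})

test_that("pose tables round-trip through long-format delimited text", {
  co <- generateCohort(generatorConfig(nCompounds = 12, seed = 8))
  pt <- co@poseTables[["PLANTS"]]
  f <- withr::local_tempfile(fileext = ".tsv")
  writePoseTable(pt, f)
  back <- readPoseTable(f)
  expect_equal(engine(back), "PLANTS")
  expect_setequal(scoreNames(back), scoreNames(pt))
  a <- featureValues(averagePoseFeatures(pt))
  b <- featureValues(averagePoseFeatures(back))
  expect_equal(b[rownames(a), colnames(a)], a, tolerance = 1e-9)
})

test_that("consensus assembly concatenates engine blocks over the docked intersection", {
  co <- sharedCohort()
  mats <- lapply(co@poseTables, averagePoseFeatures)
  suppressMessages(cons <- assembleConsensusFeatures(mats))
  expect_equal(ncol(cons), 26 + 55 + 26)
  idSets <- lapply(mats, compoundIds)
  expect_setequal(compoundIds(cons), Reduce(intersect, idSets))
  expect_error(assembleConsensusFeatures(mats[1]), "at least 2")
})

test_that("consensus assembly works with a single shared compound and fails with none", {
  m1 <- methods::new("FeatureMatrix",
                     values = matrix(1, 1, 1, dimnames = list("A", "E1.s")),
                     provenance = "sb_score", metadata = list(engine = "E1"))
  m2 <- methods::new("FeatureMatrix",
                     values = matrix(2, 2, 1, dimnames = list(c("A", "B"), "E2.s")),
                     provenance = "sb_score", metadata = list(engine = "E2"))
  suppressMessages(cons <- assembleConsensusFeatures(list(m1, m2)))
  expect_equal(dim(cons), c(1L, 2L))
  m3 <- methods::new("FeatureMatrix",
                     values = matrix(3, 1, 1, dimnames = list("Z", "E3.s")),
                     provenance = "sb_score", metadata = list(engine = "E3"))
  expect_error(assembleConsensusFeatures(list(m1, m3)), "no compounds shared")
})

test_that("missing compounds are dropped with a message or raised as errors", {
  pt <- handPoseTable()
  expect_message(bestPoseFeatures(pt, compounds = c("C1", "C2")), "no poses")
  expect_error(bestPoseFeatures(pt, missing = "error", compounds = c("C1", "C2")),
               "without poses")
})
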