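test_that("generator config validates its fields by name", {
  expect_error(generatorConfig(nCompounds = -5), "nCompounds")
  expect_error(generatorConfig(binderFraction = 1.2), "binderFraction")
  expect_error(generatorConfig(undockedFraction = 1), "undockedFraction")
  expect_error(generatorConfig(nPoses = 0), "nPoses")
  expect_error(generatorConfig(poseNoiseSd = -1), "poseNoiseSd")
  expect_error(generatorConfig(engines = character(0)), "engines")
  expect_s4_class(generatorConfig(), "GeneratorConfig")
})

test_that("identical config and seed give identical cohorts and pose tables", {
  cfg <- generatorConfig(nCompounds = 60, seed = 99)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a@compounds, b@compounds)
  expect_identical(a@activities, b@activities)
  expect_identical(poseScores(a@poseTables[["GOLD"]]), poseScores(b@poseTables[["GOLD"]]))
})

test_that("empty cohort request returns an empty cohort without error", {
  co <- generateCohort(generatorConfig(nCompounds = 0, seed = 1))
  expect_equal(nrow(co@compounds), 0)
  expect_equal(nrow(co@activities), 0)
})

test_that("class balance follows the configured binder fraction binomially", {
  co <- generateCohort(generatorConfig(nCompounds = 100, binderFraction = 0.5, seed = 7),
                       poses = FALSE)
  nb <- sum(co@compounds$label == "binder")
  expect_equal(nrow(co@compounds), 100)
  # 99.99% binomial band around 50
  expect_gt(nb, 30); expect_lt(nb, 70)
})

test_that("emitted pK is a monotone function of the latent affinity", {
  co <- sharedCohort()
  expect_gte(cor(co@truth$affinity, co@truth$pK), 0.9)
  expect_true(all(co@compounds$label == ifelse(co@compounds$pK >= 5, "binder", "non-binder")))
})

test_that("generated structures are valid and pK mass sits near the threshold", {
  co <- sharedCohort()
  canon <- standardizeStructure(co@compounds$smiles)
  expect_false(anyNA(canon))
  expect_lt(abs(median(co@compounds$pK) - 5.0), 1.0)
})

test_that("zero lipophilicity shift removes the class logP contrast", {
  diffs <- vapply(1:10, function(s) {
    co <- generateCohort(generatorConfig(nCompounds = 150, lipophilicityShift = 0,
                                         seed = 500 + s), poses = FALSE)
    binder <- co@truth$label == "binder"
    (mean(co@truth$logP[binder]) - mean(co@truth$logP[!binder])) /
      stats::sd(co@truth$logP)
  }, numeric(1))
  # pooled standardized effect indistinguishable from zero
  expect_lt(abs(mean(diffs)), 0.15)
  # and, for contrast, the default shift produces a clear positive effect
  co <- sharedCohort()
  binder <- co@truth$label == "binder"
  d <- (mean(co@truth$logP[binder]) - mean(co@truth$logP[!binder])) / stats::sd(co@truth$logP)
  expect_gt(d, 0.5)
})

test_that("pose tables conserve pose counts per compound, isomer and engine", {
  co <- sharedCohort()
  cfg <- co@params$config
  for (e in names(co@poseTables)) {
    sc <- poseScores(co@poseTables[[e]])
    counts <- table(paste(sc$compound_id, sc$isomer_id))
    expect_true(all(counts == cfg@nPoses))
    expect_true(all(sort(unique(sc$pose_rank)) == seq_len(cfg@nPoses)))
  }
})

test_that("zero pose noise collapses all poses of an isomer to identical scores", {
  cfg <- generatorConfig(nCompounds = 25, poseNoiseSd = 0, seed = 5)
  co <- generateCohort(cfg)
  pt <- co@poseTables[["PLANTS"]]
  bp <- featureValues(bestPoseFeatures(pt))
  av <- featureValues(averagePoseFeatures(pt))
  expect_equal(av, bp[rownames(av), colnames(av)], tolerance = 1e-12)
  sc <- poseScores(pt)
  one <- sc[sc$isomer_id == sc$isomer_id[1], scoreNames(pt)]
  expect_true(all(apply(one, 2, function(v) max(v) - min(v)) < 1e-12))
})

test_that("undocked compounds follow a reproducible seeded binomial draw", {
  cfg <- generatorConfig(nCompounds = 1000, seed = 21, undockedFraction = 0.024)
  co1 <- generateCohort(cfg)
  co2 <- generateCohort(cfg)
  n1 <- length(unique(poseScores(co1@poseTables[["LiGen"]])$compound_id))
  expect_identical(n1, length(unique(poseScores(co2@poseTables[["LiGen"]])$compound_id)))
  # around 2.4% missing: 99.99% binomial band
  expect_gt(n1, 1000 - 45); expect_lt(n1, 1000)
})

test_that("rescoring columns correlate with the latent affinity in the loaded direction", {
  co <- sharedCohort()
  pt <- co@poseTables[["PLANTS"]]
  av <- featureValues(averagePoseFeatures(pt))
  aff <- co@truth$affinity[match(rownames(av), co@truth$compound_id)]
  dirs <- scoreDirections(pt)
  primary <- paste0("PLANTS.", scoreNames(pt)[1])
  rescoreCols <- paste0("PLANTS.", names(dirs)[dirs == "higher"])
  cors <- cor(av, aff)[, 1]
  expect_true(all(cors[rescoreCols] > 0))     # positive loadings
  expect_lt(cors[primary], 0)                  # lower-is-better primary
})

test_that("averaging over poses denoises relative to best-pose selection", {
  co <- sharedCohort()
  pt <- co@poseTables[["GOLD"]]
  col <- paste0("GOLD.", scoreNames(pt)[2])
  av <- featureValues(averagePoseFeatures(pt))[, col]
  bp <- featureValues(bestPoseFeatures(pt))[, col]
  aff <- co@truth$affinity[match(names(av), co@truth$compound_id)]
  # residual spread around the affinity signal is smaller for the average
  resAV <- stats::sd(stats::resid(stats::lm(av ~ aff)))
  resBP <- stats::sd(stats::resid(stats::lm(bp[names(av)] ~ aff)))
  expect_lt(resAV, resBP)
})

test_that("external sets shift away from the training cohort as dissimilarity rises", {
  co <- sharedCohort()
  ref <- fingerprintMatrix(co@compounds$smiles, co@compounds$compound_id)
  med <- vapply(c("low", "high"), function(d) {
    ext <- generateExternalSet(generatorConfig(nCompounds = 120, seed = 77), d,
                               poses = FALSE)
    fp <- fingerprintMatrix(ext@compounds$smiles, ext@compounds$compound_id)
    median(hergml:::.nearestTanimoto(fp, ref))
  }, numeric(1))
  expect_gt(med[["low"]], med[["high"]])

  cfgE <- generatorConfig(nCompounds = 40, seed = 3)
  e1 <- generateExternalSet(cfgE, "medium", poses = FALSE)
  e2 <- generateExternalSet(cfgE, "medium", poses = FALSE)
  expect_identical(e1@compounds, e2@compounds)
  e0 <- generateExternalSet(generatorConfig(nCompounds = 0, seed = 3), "high")
  expect_equal(nrow(e0@compounds), 0)
})

test_that("unknown engines are rejected", {
  co <- generateCohort(generatorConfig(nCompounds = 5, seed = 1), poses = FALSE)
  expect_error(generatePoseScores(co, "Vina", co@params$config), "unknown engine")
})

test_that("LiGen mode carries the pharmacophore block for 55 columns; others 26", {
  co <- sharedCohort()
  expect_length(scoreNames(co@poseTables[["LiGen"]]), 55)
  expect_length(scoreNames(co@poseTables[["PLANTS"]]), 26)
  expect_length(scoreNames(co@poseTables[["GOLD"]]), 26)
})
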