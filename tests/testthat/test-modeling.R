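# Small deterministic feature fixtures for classifier behaviour.
toyFeatures <- function(n = 60, seed = 31) {
  set.seed(seed)
  x <- cbind(f1 = stats::rnorm(n), f2 = stats::rnorm(n), f3 = stats::rnorm(n))
  rownames(x) <- sprintf("T%03d", seq_len(n))
  labels <- ifelse(x[, "f1"] > 0, "binder", "non-binder")
  fm <- methods::new("FeatureMatrix", values = x,
                     provenance = rep("lb_physchem", 3), metadata = list())
  list(features = fm, labels = labels)
}

test_that("training is deterministic under a fixed seed", {
  toy <- toyFeatures()
  b1 <- trainClassifier(toy$features, toy$labels, modelSpec(seed = 7))
  b2 <- trainClassifier(toy$features, toy$labels, modelSpec(seed = 7))
  p1 <- predict(b1, toy$features)
  p2 <- predict(b2, toy$features)
  expect_identical(p1, p2)
  b3 <- trainClassifier(toy$features, toy$labels, modelSpec(seed = 8))
  expect_false(identical(predict(b3, toy$features)$probability, p1$probability))
})

test_that("a threshold-separable toy is fit perfectly on its training data", {
  toy <- toyFeatures()
  b <- trainClassifier(toy$features, toy$labels, modelSpec(seed = 1))
  p <- predict(b, toy$features)
  expect_identical(p$label, unname(toy$labels))
  expect_true(all(p$probability >= 0 & p$probability <= 1))
  imp <- featureImportance(b)
  expect_equal(names(imp)[1], "f1")     # the separating feature dominates
})

test_that("single-class labels are rejected", {
  toy <- toyFeatures()
  expect_error(trainClassifier(toy$features, rep("binder", 60), modelSpec()),
               "both classes")
})

test_that("prediction enforces the training feature schema", {
  toy <- toyFeatures()
  b <- trainClassifier(toy$features, toy$labels, modelSpec(seed = 2))
  v <- featureValues(toy$features)
  expect_error(predict(b, v[, 1:2]), "missing.*f3")
  extra <- cbind(v, f9 = 1)
  expect_error(predict(b, extra), "extra.*f9")
  # column order never matters
  expect_equal(predict(b, v[, c(3, 1, 2)]), predict(b, v))
})

test_that("identical feature rows receive identical predictions; labels follow the >= 0.5 rule", {
  x <- matrix(0, nrow = 8, ncol = 1, dimnames = list(paste0("r", 1:8), "f"))
  labels <- rep(c("binder", "non-binder"), 4)   # feature carries no signal
  fm <- methods::new("FeatureMatrix", values = x,
                     provenance = "lb_physchem", metadata = list())
  b <- trainClassifier(fm, labels, modelSpec(nTrees = 50, seed = 3))
  p <- predict(b, fm)
  expect_equal(length(unique(p$probability)), 1)
  expect_identical(p$label, ifelse(p$probability >= 0.5, "binder", "non-binder"))
  # the boundary itself is assigned to binder
  expect_equal(unname(confusionCounts("non-binder", 0.5)[["FP"]]), 1L)
})

test_that("stratified folds balance sizes and classes; predictions cover rows once", {
  toy <- toyFeatures(n = 83)
  r <- crossValidate(toy$features, toy$labels, modelSpec(seed = 5))
  pred <- attr(r, "predictions")
  expect_equal(nrow(pred), 83)
  expect_equal(anyDuplicated(pred$compound_id), 0)
  sizes <- table(pred$fold)
  expect_lte(max(sizes) - min(sizes), 2)        # <=1 per class stratum
  byFold <- table(pred$fold, pred$truth)
  expect_true(all(byFold > 0))
  expect_error(crossValidate(toy$features, toy$labels, modelSpec(), nFolds = 100),
               "at least")
})

test_that("a perfectly separable toy reaches CV MCC 1", {
  set.seed(41)
  x <- cbind(f = c(stats::rnorm(40, -4), stats::rnorm(40, 4)))
  rownames(x) <- sprintf("S%03d", 1:80)
  labels <- rep(c("non-binder", "binder"), each = 40)
  fm <- methods::new("FeatureMatrix", values = x,
                     provenance = "lb_physchem", metadata = list())
  r <- crossValidate(fm, labels, modelSpec(seed = 6))
  expect_equal(metrics(r)[["MCC"]], 1)
})

test_that("CV metrics are invariant to row permutation", {
  toy <- toyFeatures(n = 70)
  r1 <- crossValidate(toy$features, toy$labels, modelSpec(seed = 9))
  perm <- sample(70)
  fmP <- methods::new("FeatureMatrix", values = featureValues(toy$features)[perm, ],
                      provenance = rep("lb_physchem", 3), metadata = list())
  r2 <- crossValidate(fmP, toy$labels[perm], modelSpec(seed = 9))
  expect_equal(metrics(r1), metrics(r2), tolerance = 1e-12)
})

test_that("MaxMin diversity splitting picks the structural outlier", {
  # two identical fingerprints plus one distinct: hand-enumerable MaxMin
  fp <- rbind(twin1 = c(1, 1, 1, 0, 0, 0),
              twin2 = c(1, 1, 1, 0, 0, 0),
              lone  = c(0, 0, 0, 1, 1, 1))
  # whatever the seeded first pick, a 2-compound test set must contain `lone`
  for (s in 1:5) {
    sp <- diversitySplit(fp, testFraction = 0.67, seed = s)
    expect_length(sp$test, 2)
    expect_true("lone" %in% sp$test)
  }
  # when the seed lands on a twin, the very next MaxMin pick is the outlier
  sp1 <- diversitySplit(fp, testFraction = 0.67, seed = 1)
  if (sp1$test[1] %in% c("twin1", "twin2")) expect_equal(sp1$test[2], "lone")
  # smallest possible test set has exactly one id
  expect_length(diversitySplit(fp, testFraction = 0.01, seed = 1)$test, 1)
  expect_identical(diversitySplit(fp, 0.5, seed = 3), diversitySplit(fp, 0.5, seed = 3))
})

test_that("consensus voting follows the minimum-vote rule", {
  expect_equal(consensusPredict(rbind(c("binder", "binder", "binder", "non-binder", "non-binder")),
                                minVotes = 3), "binder")
  expect_equal(consensusPredict(rbind(c("binder", "binder", "non-binder", "non-binder", "non-binder")),
                                minVotes = 3), "non-binder")
  expect_equal(consensusPredict(rbind(rep("non-binder", 5)), minVotes = 3), "non-binder")
  set.seed(17)
  votes <- matrix(randomLabels(60), nrow = 12)
  anyB <- apply(votes == "binder", 1, any)
  allB <- apply(votes == "binder", 1, all)
  expect_equal(consensusPredict(votes, minVotes = 1) == "binder", anyB)
  expect_equal(consensusPredict(votes, minVotes = ncol(votes)) == "binder", allB)
})
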