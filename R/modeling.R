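# Random-forest classification over any feature assembly: training with a
# strict feature schema, prediction, stratified ten-fold cross-validation,
# diversity-based (MaxMin) splitting and minimum-vote consensus.

#' Random-forest model settings
#'
#' @param nTrees number of trees (default 100).
#' @param maxDepth maximal tree depth; 0 means unlimited.
#' @param seed integer seed making training deterministic.
#' @return list of validated settings.
#' @export
modelSpec <- function(nTrees = 100L, maxDepth = 0L, seed = 1L) {
  stopIfNot(nTrees >= 1, "nTrees must be >= 1")
  stopIfNot(maxDepth >= 0, "maxDepth must be >= 0 (0 = unlimited)")
  list(nTrees = as.integer(nTrees), maxDepth = as.integer(maxDepth),
       seed = as.integer(seed), positiveClass = "binder")
}

#' Train a random-forest binder classifier
#'
#' Fits a probability forest on the feature matrix. The bundle records the
#' exact feature schema (prediction refuses non-matching inputs), optional
#' training fingerprints and a fitted applicability-domain reference.
#' Feature importances (mean impurity decrease) are available via
#' [featureImportance()].
#'
#' @param features a [FeatureMatrix-class] (no missing values).
#' @param labels `"binder"`/`"non-binder"` labels parallel to the rows.
#' @param spec settings from [modelSpec()].
#' @param fingerprints optional ECFP matrix (rows matching `features`) kept
#'   for applicability-domain and diversity use.
#' @param adRef optional fitted [ADReference-class].
#' @return A [ModelBundle-class].
#' @export
trainClassifier <- function(features, labels, spec = modelSpec(),
                            fingerprints = NULL, adRef = NULL) {
  x <- .featureMatrixOf(features)
  labels <- .asLabels(labels)
  stopIfNot(nrow(x) == length(labels), "labels must parallel feature rows")
  stopIfNot(length(unique(labels)) == 2, "training needs both classes present")
  stopIfNot(!anyNA(x), "feature matrix contains missing values")
  y <- factor(labels, levels = .LABELS)
  fit <- ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = spec$nTrees,
    max.depth = if (spec$maxDepth > 0) spec$maxDepth else NULL,
    probability = TRUE, importance = "impurity",
    seed = spec$seed, num.threads = 1,
    respect.unordered.factors = "order")
  prov <- if (methods::is(features, "FeatureMatrix")) features@provenance else rep("lb_physchem", ncol(x))
  fp <- if (is.null(fingerprints)) matrix(integer(0), nrow = 0, ncol = 0) else as.matrix(fingerprints)
  methods::new("ModelBundle", fit = fit, featureNames = colnames(x),
               provenance = prov, fingerprints = fp,
               adRef = adRef, spec = spec)
}

#' Feature importance of a trained bundle
#'
#' Mean impurity decrease, as recorded by the forest.
#'
#' @param bundle a [ModelBundle-class].
#' @return Named numeric vector, decreasing.
#' @export
featureImportance <- function(bundle) {
  sort(ranger::importance(bundle@fit), decreasing = TRUE)
}

#' Predict binder labels and probabilities
#'
#' The input columns must match the training schema exactly (any order);
#' missing or extra columns raise an error naming them. The label is
#' `"binder"` iff the binder probability is at least 0.5 (the boundary is
#' assigned to binder, favouring sensitivity under binder-heavy class
#' balance).
#'
#' @param object a [ModelBundle-class].
#' @param features a [FeatureMatrix-class] or matrix.
#' @return data.frame with `compound_id`, `label`, `probability`.
#' @export
setMethod("predict", "ModelBundle", function(object, features, ...) {
  x <- .featureMatrixOf(features)
  miss <- setdiff(object@featureNames, colnames(x))
  extra <- setdiff(colnames(x), object@featureNames)
  stopIfNot(length(miss) == 0 && length(extra) == 0,
            sprintf("feature schema mismatch; missing: [%s], extra: [%s]",
                    paste(utils::head(miss, 5), collapse = ", "),
                    paste(utils::head(extra, 5), collapse = ", ")))
  x <- x[, object@featureNames, drop = FALSE]
  pr <- stats::predict(object@fit, data = as.data.frame(x), num.threads = 1)$predictions
  p <- pr[, "binder"]
  data.frame(compound_id = rownames(x) %||% as.character(seq_len(nrow(x))),
             label = ifelse(p >= 0.5, "binder", "non-binder"),
             probability = as.numeric(p), stringsAsFactors = FALSE)
})

# Seeded stratified fold assignment: within each class, rows (ordered by
# their identifiers, so the assignment depends only on id, class and seed —
# not on row order) are dealt a seeded random permutation of round-robin
# fold numbers. Fold sizes differ by at most one and every fold sees both
# classes whenever n_class >= nFolds.
.stratifiedFolds <- function(labels, ids, nFolds, seed) {
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[order(ids[idx])]
      folds[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
  })
  folds
}

#' Stratified ten-fold cross-validation
#'
#' Splits the data into seeded stratified folds, trains on each training
#' partition and pools the out-of-fold predictions into a single
#' [EvaluationReport-class] (each compound predicted exactly once).
#'
#' @param features a [FeatureMatrix-class].
#' @param labels class labels.
#' @param spec settings from [modelSpec()].
#' @param nFolds number of folds (default 10).
#' @param seed fold-assignment seed (default: `spec$seed`).
#' @return An [EvaluationReport-class]; the pooled out-of-fold predictions
#'   are attached as attribute `"predictions"`.
#' @export
crossValidate <- function(features, labels, spec = modelSpec(), nFolds = 10L,
                          seed = spec$seed) {
  x <- .featureMatrixOf(features)
  labels <- .asLabels(labels)
  n <- nrow(x)
  stopIfNot(n >= nFolds, sprintf("need at least %d rows for %d-fold CV", nFolds, nFolds))
  folds <- .stratifiedFolds(labels, rownames(x) %||% as.character(seq_len(n)),
                            nFolds, seed)
  prob <- numeric(n)
  for (f in seq_len(nFolds)) {
    tr <- folds != f
    fit <- ranger::ranger(
      x = as.data.frame(x[tr, , drop = FALSE]),
      y = factor(labels[tr], levels = .LABELS),
      num.trees = spec$nTrees,
      max.depth = if (spec$maxDepth > 0) spec$maxDepth else NULL,
      probability = TRUE, seed = deriveSeed(spec$seed, f), num.threads = 1)
    pr <- stats::predict(fit, data = as.data.frame(x[!tr, , drop = FALSE]),
                         num.threads = 1)$predictions
    prob[!tr] <- pr[, "binder"]
  }
  pred <- ifelse(prob >= 0.5, "binder", "non-binder")
  report <- evaluationReport(labels, pred, prob)
  attr(report, "predictions") <- data.frame(
    compound_id = rownames(x) %||% as.character(seq_len(n)),
    fold = folds, truth = labels, label = pred, probability = prob,
    stringsAsFactors = FALSE)
  report
}

#' Diversity-based train/test split (MaxMin picking)
#'
#' Picks a maximally diverse test set on Tanimoto distance: the first pick
#' is seeded-random, then each following pick maximizes its minimum distance
#' to the already picked set (ties broken by row order) until the requested
#' test size is reached. The picked compounds form the test set.
#'
#' @param fingerprints 0/1 matrix with compound rownames.
#' @param testFraction fraction of compounds picked for testing, in (0,1).
#' @param seed integer seed for the first pick.
#' @return list with `train` and `test` compound-id vectors.
#' @export
diversitySplit <- function(fingerprints, testFraction = 0.3, seed = 1L) {
  fp <- as.matrix(fingerprints)
  stopIfNot(testFraction > 0 && testFraction < 1, "testFraction must lie in (0,1)")
  n <- nrow(fp)
  ids <- rownames(fp) %||% as.character(seq_len(n))
  size <- max(1L, round(n * testFraction))
  first <- withSeed(seed, sample.int(n, 1))
  picked <- first
  # running minimum distance of every compound to the picked set
  minDist <- 1 - .tanimotoTo(fp, fp[first, ])
  while (length(picked) < size) {
    minDist[picked] <- -1
    nxt <- which.max(minDist)
    picked <- c(picked, nxt)
    minDist <- pmin(minDist, 1 - .tanimotoTo(fp, fp[nxt, ]))
  }
  list(train = ids[-picked], test = ids[picked])
}

# Tanimoto of every row of `fp` to a single fingerprint vector.
.tanimotoTo <- function(fp, v) {
  inter <- as.numeric(fp %*% v)
  un <- rowSums(fp) + sum(v) - inter
  ifelse(un == 0, 1, inter / pmax(un, 1))
}

#' Minimum-vote consensus over model predictions
#'
#' A compound is called binder iff at least `minVotes` of the models voted
#' binder. With `minVotes = 1` this is a logical OR over models, with
#' `minVotes = n models` a logical AND.
#'
#' @param votes a character matrix or data.frame (compounds x models) of
#'   labels, or a list of per-model label vectors.
#' @param minVotes minimum number of binder votes (default 3).
#' @return Character vector of consensus labels.
#' @examples
#' consensusPredict(rbind(c("binder", "binder", "binder", "non-binder", "non-binder")))
#' @export
consensusPredict <- function(votes, minVotes = 3L) {
  if (is.list(votes) && !is.data.frame(votes)) votes <- do.call(cbind, votes)
  votes <- as.matrix(votes)
  stopIfNot(ncol(votes) >= 1, "need at least one vote")
  apply(votes, 1, function(v) {
    v <- .asLabels(v)
    if (sum(v == "binder") >= minVotes) "binder" else "non-binder"
  })
}
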