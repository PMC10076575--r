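# Shared fixtures, memoized so expensive chemistry runs once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A mid-sized cohort under generator defaults, used across test files.
sharedCohort <- function() {
  memo("cohort", generateCohort(generatorConfig(nCompounds = 400, seed = 42)))
}

sharedLBFeatures <- function() {
  memo("lb", {
    co <- sharedCohort()
    computeLBFeatures(co@compounds$smiles, ids = co@compounds$compound_id)
  })
}

# Hand-written two-isomer pose fixture (2 scores, 2 poses per isomer).
# Isomer i1: rank-1 row (scoreA -9, scoreB 2); isomer i2: rank-1 (-5, 4).
# Best-pose expectation: scoreA (-9 + -5)/2 = -7, scoreB (2 + 4)/2 = 3.
# Pooled average: scoreA mean(-9,-7,-5,-3) = -6, scoreB mean(2,1,4,5) = 3.
handPoseTable <- function() {
  rows <- data.frame(
    compound_id = "C1",
    isomer_id = c("C1_i1", "C1_i1", "C1_i2", "C1_i2"),
    pose_rank = c(1L, 2L, 1L, 2L),
    scoreA = c(-9, -7, -5, -3),
    scoreB = c(2, 1, 4, 5),
    stringsAsFactors = FALSE)
  validatePoseTable(rows, engine = "ENG")
}

# Independent brute-force metric oracle: literal formulas from raw labels.
bruteMetrics <- function(truth, pred) {
  TP <- sum(truth == "binder" & pred == "binder")
  TN <- sum(truth == "non-binder" & pred == "non-binder")
  FP <- sum(truth == "non-binder" & pred == "binder")
  FN <- sum(truth == "binder" & pred == "non-binder")
  den <- sqrt(as.numeric(TP + FP) * as.numeric(TP + FN) *
                as.numeric(TN + FP) * as.numeric(TN + FN))
  c(TP = TP, TN = TN, FP = FP, FN = FN,
    MCC = if (den == 0) 0 else (TN * TP - FN * FP) / den,
    ACC = (TP + TN) / length(truth),
    precision = if (TP + FP == 0) 0 else TP / (TP + FP),
    SE = if (TP + FN == 0) 0 else TP / (TP + FN),
    SP = if (TN + FP == 0) 0 else TN / (TN + FP))
}

# Independent AUC oracle: enumerate all binder/non-binder pairs.
bruteAUC <- function(truth, prob) {
  pos <- prob[truth == "binder"]; neg <- prob[truth == "non-binder"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive CFS optimum over all non-empty subsets (small p only).
bruteBestSubset <- function(x, y) {
  p <- ncol(x)
  best <- list(merit = -Inf, subset = character(0))
  for (mask in seq_len(2^p - 1)) {
    subset <- colnames(x)[bitwAnd(mask, 2^(seq_len(p) - 1)) > 0]
    m <- cfsMerit(subset, x, y)
    if (m > best$merit + 1e-12) best <- list(merit = m, subset = subset)
  }
  best
}

randomLabels <- function(n, pBinder = 0.5) {
  ifelse(stats::runif(n) < pBinder, "binder", "non-binder")
}
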