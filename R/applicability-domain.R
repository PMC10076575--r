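# Applicability domain: four methods plus their minimum-vote consensus.
#   1. similarity  — nearest-neighbour ECFP Tanimoto strictly above a cutoff;
#   2. range       — inside the training min/max box of the first two
#                    standardized PCA components;
#   3. Euclidean   — standardized-space distance to the training centroid at
#                    most the chosen percentile of training distances;
#   4. density     — Gaussian product-kernel density on the leading PCA
#                    components at least the cutoff covering the chosen
#                    percentage of training points.
# A compound is inside the domain when at least minMethods methods agree.

#' Fit an applicability-domain reference on training data
#'
#' @param features training [FeatureMatrix-class] or matrix (the descriptors
#'   the model was trained on).
#' @param fingerprints training ECFP 0/1 matrix (similarity method).
#' @param similarityCutoff nearest-neighbour Tanimoto cutoff; strictly
#'   greater-than (default 0.7).
#' @param distancePercentile training-distance percentile bounding the
#'   Euclidean method (default 95).
#' @param densityCoverage percentage of training points the density cutoff
#'   must cover (default 95).
#' @param minMethods methods required for consensus, 1..4 (default 3).
#' @param nDensityComponents PCA components carrying the kernel density
#'   estimate (default 5; capped at the feature count). Working on a few
#'   leading components avoids high-dimensional kernel degeneracy.
#' @return An [ADReference-class].
#' @export
adReference <- function(features, fingerprints,
                        similarityCutoff = 0.7, distancePercentile = 95,
                        densityCoverage = 95, minMethods = 3L,
                        nDensityComponents = 5L) {
  x <- .featureMatrixOf(features)
  fp <- as.matrix(fingerprints)
  stopIfNot(nrow(fp) > 0, "empty training fingerprint set")
  stopIfNot(minMethods >= 1 && minMethods <= 4, "minMethods must lie in 1..4")
  sds <- apply(x, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  x <- x[, keep, drop = FALSE]
  stopIfNot(ncol(x) > 0, "all descriptors constant; cannot fit a domain")
  xs <- standardizeColumns(x)
  center <- attr(xs, "center"); scale <- attr(xs, "scale")
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  k2 <- min(2L, ncol(pc$rotation))
  pcRange <- apply(pc$x[, seq_len(k2), drop = FALSE], 2, range)
  dists <- sqrt(rowSums(xs^2))
  dThr <- stats::quantile(dists, distancePercentile / 100, names = FALSE)
  kd <- min(nDensityComponents, ncol(pc$rotation))
  dTrain <- pc$x[, seq_len(kd), drop = FALSE]
  bw <- .silvermanBandwidth(dTrain)
  dens <- .gaussKde(dTrain, dTrain, bw)
  dCut <- stats::quantile(dens, 1 - densityCoverage / 100, names = FALSE)
  methods::new("ADReference",
               fingerprints = fp, center = center, scale = scale,
               rotation = pc$rotation, pcRange = pcRange,
               distanceThreshold = dThr, densityCutoff = dCut,
               densityTrain = dTrain, bandwidth = bw,
               similarityCutoff = similarityCutoff,
               distancePercentile = distancePercentile,
               densityCoverage = densityCoverage,
               minMethods = as.integer(minMethods),
               featureNames = colnames(x))
}

# Multivariate rule-of-thumb bandwidth per dimension.
.silvermanBandwidth <- function(x) {
  n <- nrow(x); d <- ncol(x)
  fac <- (4 / (d + 2))^(1 / (d + 4)) * n^(-1 / (d + 4))
  pmax(apply(x, 2, stats::sd) * fac, .Machine$double.eps)
}

# Gaussian product-kernel density of query points against training points,
# chunked over query rows to bound memory.
.gaussKde <- function(query, train, bw, chunk = 512L) {
  n <- nrow(train)
  const <- prod(bw) * (2 * pi)^(ncol(train) / 2)
  out <- numeric(nrow(query))
  starts <- seq(1, nrow(query), by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1, nrow(query))
    logs <- matrix(0, length(rows), n)
    for (j in seq_len(ncol(train))) {
      z <- outer(query[rows, j], train[, j], "-") / bw[j]
      logs <- logs - z^2 / 2
    }
    out[rows] <- rowSums(exp(logs)) / (n * const)
  }
  out
}

.projectFeatures <- function(x, ref, k) {
  x <- .featureMatrixOf(x)
  stopIfNot(all(ref@featureNames %in% colnames(x)),
            "input lacks the descriptors the domain was fitted on")
  xs <- standardizeColumns(x[, ref@featureNames, drop = FALSE],
                           center = ref@center, scale = ref@scale)
  list(std = xs, pc = xs %*% ref@rotation[, seq_len(k), drop = FALSE])
}

#' Similarity applicability-domain method
#'
#' Inside iff the maximal Tanimoto similarity to any training fingerprint is
#' strictly greater than the cutoff.
#'
#' @param fingerprints query 0/1 matrix (or a single vector).
#' @param ref an [ADReference-class].
#' @return data.frame with `ok` and `nearest_neighbor_tc`.
#' @export
adSimilarity <- function(fingerprints, ref) {
  fp <- if (is.null(dim(fingerprints))) matrix(fingerprints, nrow = 1) else as.matrix(fingerprints)
  stopIfNot(nrow(ref@fingerprints) > 0, "reference has no training fingerprints")
  tc <- .nearestTanimoto(fp, ref@fingerprints)
  data.frame(ok = tc > ref@similarityCutoff, nearest_neighbor_tc = tc)
}

#' Range (PCA box) applicability-domain method
#'
#' Inside iff both leading standardized PCA coordinates lie within the
#' training minimum/maximum (closed interval: boundary points are inside).
#'
#' @param features query features (matching the fitted descriptor names).
#' @param ref an [ADReference-class].
#' @return Logical vector.
#' @export
adRange <- function(features, ref) {
  k2 <- ncol(ref@pcRange)
  sc <- .projectFeatures(features, ref, k2)$pc
  ok <- rep(TRUE, nrow(sc))
  for (j in seq_len(k2)) {
    # closed interval with a numerical guard so training extremes re-project
    # onto (not just outside) their own boundary
    eps <- 1e-8 * (ref@pcRange[2, j] - ref@pcRange[1, j] + 1)
    ok <- ok & sc[, j] >= ref@pcRange[1, j] - eps & sc[, j] <= ref@pcRange[2, j] + eps
  }
  ok
}

#' Euclidean-distance applicability-domain method
#'
#' Inside iff the standardized-space distance to the training centroid is at
#' most the fitted percentile of training distances.
#'
#' @inheritParams adRange
#' @return Logical vector.
#' @export
adEuclidean <- function(features, ref) {
  xs <- .projectFeatures(features, ref, 1)$std
  sqrt(rowSums(xs^2)) <= ref@distanceThreshold
}

#' Probability-density applicability-domain method
#'
#' Inside iff the Gaussian kernel density estimate at the query point (on
#' the leading PCA components) reaches the cutoff that covers the configured
#' share of training points.
#'
#' @inheritParams adRange
#' @return Logical vector.
#' @export
adDensity <- function(features, ref) {
  kd <- ncol(ref@densityTrain)
  sc <- .projectFeatures(features, ref, kd)$pc
  .gaussKde(sc, ref@densityTrain, ref@bandwidth) >= ref@densityCutoff
}

#' Applicability-domain consensus
#'
#' @param flags logical vector of exactly four method verdicts (or a 4-column
#'   matrix, one row per compound).
#' @param minMethods methods required (default 3).
#' @return Logical scalar/vector: inside iff at least `minMethods` are TRUE.
#' @examples
#' adConsensus(c(TRUE, TRUE, TRUE, FALSE))  # TRUE
#' @export
adConsensus <- function(flags, minMethods = 3L) {
  if (is.null(dim(flags))) {
    stopIfNot(length(flags) == 4, "consensus needs exactly 4 method flags")
    return(sum(flags) >= minMethods)
  }
  stopIfNot(ncol(flags) == 4, "consensus needs exactly 4 method flags")
  rowSums(flags) >= minMethods
}

#' Full per-compound applicability-domain verdicts
#'
#' Runs all four methods and the consensus.
#'
#' @param features query descriptor matrix.
#' @param fingerprints query ECFP matrix (same rows).
#' @param ref an [ADReference-class].
#' @return data.frame with `similarity_ok`, `range_ok`, `euclidean_ok`,
#'   `density_ok`, `consensus_ok`, `nearest_neighbor_tc`.
#' @export
assessAD <- function(features, fingerprints, ref) {
  sim <- adSimilarity(fingerprints, ref)
  out <- data.frame(similarity_ok = sim$ok,
                    range_ok = adRange(features, ref),
                    euclidean_ok = adEuclidean(features, ref),
                    density_ok = adDensity(features, ref),
                    stringsAsFactors = FALSE)
  out$consensus_ok <- adConsensus(as.matrix(out), ref@minMethods)
  out$nearest_neighbor_tc <- sim$nearest_neighbor_tc
  rn <- rownames(.featureMatrixOf(features))
  if (!is.null(rn)) out <- cbind(compound_id = rn, out, stringsAsFactors = FALSE)
  out
}

#' Accuracy versus training-similarity trend
#'
#' Bins the nearest-neighbour Tanimoto similarity of test compounds to the
#' training set into fixed-width intervals and reports per-bin prediction
#' accuracy — the diagnostic showing whether a model's reliability depends
#' on structural similarity to its training set.
#'
#' @param nnTc nearest-neighbour Tanimoto per test compound (e.g. from
#'   [assessAD()]).
#' @param truth,predicted label vectors.
#' @param binWidth similarity bin width (default 0.1).
#' @return data.frame with `bin_low`, `bin_high`, `bin_mid`, `n`, `accuracy`
#'   (`NA` with `empty = TRUE` for unpopulated bins).
#' @export
trendReport <- function(nnTc, truth, predicted, binWidth = 0.1) {
  stopIfNot(length(nnTc) == length(truth) && length(truth) == length(predicted),
            "nnTc, truth and predicted must be parallel")
  breaks <- seq(0, 1, by = binWidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  lows <- utils::head(breaks, -1); highs <- utils::tail(breaks, -1)
  out <- data.frame(bin_low = lows, bin_high = highs,
                    bin_mid = (lows + highs) / 2, n = 0L,
                    accuracy = NA_real_, empty = TRUE)
  if (length(nnTc) == 0) return(out)
  t <- .asLabels(truth); p <- .asLabels(predicted)
  binIdx <- pmin(findInterval(nnTc, breaks, rightmost.closed = TRUE), length(lows))
  for (b in unique(binIdx)) {
    sel <- binIdx == b
    out$n[b] <- sum(sel)
    out$accuracy[b] <- mean(t[sel] == p[sel])
    out$empty[b] <- FALSE
  }
  out
}
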