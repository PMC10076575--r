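# Correlation-based feature-subset selection (CFS) with forward best-first
# search. Subset merit balances mean absolute feature-class correlation
# against mean absolute feature-feature correlation:
#
#   merit(S) = k * rcf / sqrt(k + k (k - 1) * rff)
#
# with k = |S|, rcf the mean |corr(feature, class)| and rff the mean
# |corr(feature_i, feature_j)| over pairs in S. Correlations are Pearson
# (point-biserial against the 0/1 class); constant features correlate 0.

.asLabel01 <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(as.numeric(labels == "binder"))
  as.numeric(labels)
}

.featureMatrixOf <- function(features) {
  if (methods::is(features, "FeatureMatrix")) featureValues(features) else as.matrix(features)
}

# merit from k, sum of class correlations and sum of pairwise correlations
# (sumRff = sum over unordered pairs, so k(k-1)*rff_bar = 2*sumRff).
.cfsMeritFromParts <- function(k, sumRcf, sumRff) {
  den <- sqrt(k + 2 * sumRff)
  ifelse(den > 0, sumRcf / den, 0)
}

#' CFS merit of a feature subset
#'
#' @param subset character vector of feature names (non-empty).
#' @param features a [FeatureMatrix-class] or numeric matrix with named
#'   columns.
#' @param labels class labels (`"binder"`/`"non-binder"`, factor, or 0/1).
#' @return The scalar merit (non-negative).
#' @examples
#' x <- cbind(a = c(0, 0, 1, 1), b = c(1, 0, 1, 0))
#' cfsMerit("a", x, c(0, 0, 1, 1))  # |corr| of a with the class = 1
#' @export
cfsMerit <- function(subset, features, labels) {
  x <- .featureMatrixOf(features)
  y <- .asLabel01(labels)
  stopIfNot(length(subset) > 0, "subset must be non-empty")
  stopIfNot(all(subset %in% colnames(x)),
            sprintf("unknown features: %s",
                    paste(setdiff(subset, colnames(x)), collapse = ", ")))
  xs <- x[, subset, drop = FALSE]
  k <- ncol(xs)
  sumRcf <- sum(abs(safeCor(xs, y)))
  sumRff <- 0
  if (k > 1) {
    rff <- abs(safeCor(xs, xs))
    sumRff <- (sum(rff) - k) / 2       # drop the unit diagonal, halve
  }
  as.numeric(.cfsMeritFromParts(k, sumRcf, sumRff))
}

#' Forward best-first feature-subset selection under the CFS merit
#'
#' Greedy best-first search over subsets: an open list of states ordered by
#' merit is repeatedly expanded from its best unexpanded state by adding
#' each unused feature; the search stops after `maxStale` consecutive
#' expansions that fail to improve the best merit found. Deterministic:
#' merit ties are broken by feature-name order. Returns the feature names of
#' the best subset found (empty, with a warning, when no feature has
#' non-zero class correlation).
#'
#' @param features a [FeatureMatrix-class] or numeric matrix with named
#'   columns (at least one).
#' @param labels class labels.
#' @param maxStale consecutive non-improving expansions tolerated (>= 1,
#'   default 5, the conventional best-first stopping patience).
#' @return Character vector of selected feature names, in inclusion order.
#' @export
bestFirstSelect <- function(features, labels, maxStale = 5L) {
  x <- .featureMatrixOf(features)
  y <- .asLabel01(labels)
  stopIfNot(ncol(x) >= 1, "need at least one feature")
  stopIfNot(maxStale >= 1, "maxStale must be >= 1")
  p <- ncol(x)
  nms <- colnames(x)
  tieRank <- integer(p); tieRank[order(nms)] <- seq_len(p)
  xs <- standardizeColumns(x)
  n <- nrow(xs)
  sy <- stats::sd(y)
  rcf <- if (is.finite(sy) && sy > 0) {
    pmin(abs(as.numeric(crossprod(xs, (y - mean(y)) / sy))) / (n - 1), 1)
  } else rep(0, p)
  rcf[!is.finite(rcf)] <- 0
  if (all(rcf == 0)) {
    warning("no feature has non-zero class correlation; returning empty selection")
    return(character(0))
  }

  corCache <- vector("list", p)         # |corr(all features, j)|, filled lazily
  corWith <- function(j) {
    if (is.null(corCache[[j]])) {
      v <- pmin(abs(as.numeric(crossprod(xs, xs[, j]))) / (n - 1), 1)
      v[!is.finite(v)] <- 0
      corCache[[j]] <<- v
    }
    corCache[[j]]
  }

  # Flat state arrays (state 1 = empty subset); children are appended in
  # blocks so an expansion is a handful of vector operations.
  parent <- 0L; added <- 0L; meritV <- 0; sumRcfV <- 0; sumRffV <- 0
  isOpen <- TRUE
  subsetOf <- function(i) {
    s <- integer(0)
    while (i > 1) { s <- c(added[i], s); i <- parent[i] }
    s
  }
  seen <- new.env(parent = emptyenv())
  bestIdx <- 1L; bestMerit <- 0
  stale <- 0L

  while (any(isOpen) && stale < maxStale) {
    om <- ifelse(isOpen, meritV, -Inf)
    mx <- max(om)
    pick <- which(om >= mx - 1e-12)
    if (length(pick) > 1) {
      tr <- ifelse(added[pick] > 0, tieRank[pmax(added[pick], 1L)], 0L)
      pick <- pick[order(tr, pick)]
    }
    i <- pick[1]
    isOpen[i] <- FALSE
    sub <- subsetOf(i)
    key <- paste0("s", paste(sort(sub), collapse = ","))
    if (exists(key, envir = seen, inherits = FALSE)) next   # duplicate subset
    assign(key, TRUE, envir = seen)
    cand <- if (length(sub)) setdiff(seq_len(p), sub) else seq_len(p)
    if (!length(cand)) { stale <- stale + 1L; next }
    sumAbs <- numeric(p)
    for (j in sub) sumAbs <- sumAbs + corWith(j)
    cRcf <- sumRcfV[i] + rcf[cand]
    cRff <- sumRffV[i] + sumAbs[cand]
    cMer <- as.numeric(.cfsMeritFromParts(length(sub) + 1, cRcf, cRff))
    nNew <- length(cand)
    parent <- c(parent, rep.int(i, nNew))
    added <- c(added, cand)
    meritV <- c(meritV, cMer)
    sumRcfV <- c(sumRcfV, cRcf)
    sumRffV <- c(sumRffV, cRff)
    isOpen <- c(isOpen, rep.int(TRUE, nNew))
    mb <- max(cMer)
    if (mb > bestMerit + 1e-12) {
      w <- which(cMer >= mb - 1e-12)
      w <- w[order(tieRank[cand[w]])][1]
      bestIdx <- length(meritV) - nNew + w
      bestMerit <- mb
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
  }
  nms[subsetOf(bestIdx)]
}
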