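# Evaluation metrics for binary binder/non-binder classification, with the
# binder class as positive: confusion counts, MCC, accuracy, precision,
# sensitivity, specificity and rank-based ROC AUC.

.LABELS <- c("binder", "non-binder")

.asLabels <- function(x) {
  if (is.logical(x)) x <- ifelse(x, "binder", "non-binder")
  if (is.numeric(x)) x <- ifelse(x >= 0.5, "binder", "non-binder")
  x <- as.character(x)
  stopIfNot(all(x %in% .LABELS),
            sprintf("labels must be 'binder'/'non-binder', got: %s",
                    paste(utils::head(setdiff(unique(x), .LABELS), 3), collapse = ", ")))
  x
}

#' Confusion counts (binder = positive class)
#'
#' @param truth,predicted equal-length label vectors
#'   (`"binder"`/`"non-binder"`).
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusionCounts <- function(truth, predicted) {
  stopIfNot(length(truth) == length(predicted),
            "truth and predicted must have equal length")
  t <- .asLabels(truth); p <- .asLabels(predicted)
  c(TP = sum(t == "binder" & p == "binder"),
    TN = sum(t == "non-binder" & p == "non-binder"),
    FP = sum(t == "non-binder" & p == "binder"),
    FN = sum(t == "binder" & p == "non-binder"))
}

#' Classification metrics from confusion counts
#'
#' Computes the Matthews correlation coefficient
#' \deqn{MCC = (TN \cdot TP - FN \cdot FP) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' together with accuracy, precision, sensitivity (SE) and specificity (SP).
#' Any metric whose denominator is zero returns the documented convention
#' value (MCC 0; precision/SE/SP 0) and is listed in the `"flags"`
#' attribute.
#'
#' @param TP,TN,FP,FN non-negative confusion counts (or a single named
#'   vector passed as `TP`).
#' @return Named numeric vector `c(MCC, ACC, precision, SE, SP)` with a
#'   `"flags"` attribute.
#' @examples
#' classificationMetrics(TP = 3, TN = 1, FP = 1, FN = 1)
#' @export
classificationMetrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (is.null(TN) && length(TP) == 4) {
    cc <- TP; TP <- cc[["TP"]]; TN <- cc[["TN"]]; FP <- cc[["FP"]]; FN <- cc[["FN"]]
  }
  stopIfNot(all(c(TP, TN, FP, FN) >= 0), "counts must be non-negative")
  n <- TP + TN + FP + FN
  stopIfNot(n > 0, "all confusion counts are zero")
  flags <- character(0)
  conv <- function(num, den, nm) {
    if (den == 0) { flags <<- c(flags, nm); return(0) }
    num / den
  }
  mccDen <- sqrt(as.numeric(TP + FP) * as.numeric(TP + FN) *
                   as.numeric(TN + FP) * as.numeric(TN + FN))
  out <- c(MCC = conv(TN * TP - FN * FP, mccDen, "MCC"),
           ACC = (TP + TN) / n,
           precision = conv(TP, TP + FP, "precision"),
           SE = conv(TP, TP + FN, "SE"),
           SP = conv(TN, TN + FP, "SP"))
  attr(out, "flags") <- flags
  out
}

#' Rank-based ROC AUC
#'
#' The probability that a randomly chosen binder receives a higher score
#' than a randomly chosen non-binder, ties counted 1/2 (equivalent to the
#' area under the ROC curve).
#'
#' @param truth label vector containing both classes.
#' @param prob numeric scores (binder probability).
#' @return AUC in `[0, 1]`.
#' @export
rocAUC <- function(truth, prob) {
  t <- .asLabels(truth)
  stopIfNot(length(t) == length(prob), "truth and prob must have equal length")
  pos <- t == "binder"
  n1 <- sum(pos); n0 <- sum(!pos)
  stopIfNot(n1 > 0 && n0 > 0, "AUC needs both classes present")
  r <- rank(prob, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build a full evaluation report
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param prob optional binder probabilities (enables AUC).
#' @return An [EvaluationReport-class].
#' @export
evaluationReport <- function(truth, predicted, prob = NULL) {
  cc <- confusionCounts(truth, predicted)
  m <- classificationMetrics(cc)
  auc <- if (!is.null(prob)) rocAUC(truth, prob) else NA_real_
  metrics <- c(m[c("MCC", "ACC")], AUC = auc,
               m[c("precision", "SE", "SP")])
  names(metrics) <- c("MCC", "ACC", "AUC", "precision", "SE", "SP")
  methods::new("EvaluationReport",
               TP = as.integer(cc[["TP"]]), TN = as.integer(cc[["TN"]]),
               FP = as.integer(cc[["FP"]]), FN = as.integer(cc[["FN"]]),
               metrics = metrics, n = as.integer(sum(cc)),
               flags = attr(m, "flags"))
}

#' Side-by-side model comparison table
#'
#' One column per report, metrics as rows — the conventional layout for
#' comparing ligand-based, best-pose, average-score and consensus models.
#'
#' @param reports named list of [EvaluationReport-class] objects.
#' @return data.frame with a `metric` column and one column per model.
#' @export
compareModels <- function(reports) {
  stopIfNot(length(reports) > 0, "no reports given")
  nm <- names(reports) %||% paste0("model", seq_along(reports))
  out <- data.frame(metric = c("MCC", "ACC", "AUC", "precision", "SE", "SP"),
                    stringsAsFactors = FALSE)
  for (i in seq_along(reports)) out[[nm[i]]] <- unname(metrics(reports[[i]])[out$metric])
  out
}

#' Serialize a report (or comparison) as delimited text / JSON
#'
#' @param x an [EvaluationReport-class] or the data.frame from
#'   [compareModels()].
#' @param file output path; extension `.json` selects JSON.
#' @export
writeReport <- function(x, file) {
  if (methods::is(x, "EvaluationReport")) {
    x <- data.frame(metric = c("TP", "TN", "FP", "FN", names(metrics(x))),
                    value = c(x@TP, x@TN, x@FP, x@FN, unname(metrics(x))),
                    stringsAsFactors = FALSE)
  }
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(x, file, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(x, file, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}
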