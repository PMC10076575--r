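# Structure-based featurization: collapse multi-pose, multi-isomer score
# tables into one row per compound, by best pose (rank-1 scores averaged over
# stereoisomers) or by the binding-space average (pooled mean over all
# poses), and assemble multi-engine consensus feature blocks.

#' Validate a long-format pose-score table
#'
#' Checks key uniqueness, pose-rank contiguity (1..n within every
#' compound/isomer group) and score-name consistency, then returns a typed
#' [PoseScoreTable-class]. Accepts either long layout (`compound_id`,
#' `isomer_id`, `engine`, `pose_rank`, `score_name`, `value`) or the wide
#' layout used internally.
#'
#' @param rows data.frame of raw pose scores.
#' @param engine engine identifier; required for wide input, inferred (and
#'   checked unique) for long input.
#' @param directions optional named character vector of score direction
#'   conventions (`"lower"`/`"higher"` is better); defaults to `"lower"` for
#'   the first score and `"higher"` otherwise.
#' @return A validated [PoseScoreTable-class].
#' @export
validatePoseTable <- function(rows, engine = NULL, directions = NULL) {
  long <- all(c("score_name", "value") %in% names(rows))
  if (long) {
    stopIfNot(all(c("compound_id", "isomer_id", "pose_rank") %in% names(rows)),
              "long pose table needs compound_id, isomer_id, pose_rank, score_name, value")
    if ("engine" %in% names(rows)) {
      eng <- unique(rows$engine)
      stopIfNot(length(eng) <= 1, sprintf(
        "pose table mixes engines (%s); validate one engine at a time",
        paste(eng, collapse = ", ")))
      if (is.null(engine)) engine <- eng
    }
    key <- paste(rows$compound_id, rows$isomer_id, rows$pose_rank, rows$score_name)
    dup <- duplicated(key)
    stopIfNot(!any(dup), sprintf("duplicate pose-score keys: %s",
                                 paste(utils::head(unique(key[dup]), 5), collapse = "; ")))
    wide <- stats::reshape(rows[, c("compound_id", "isomer_id", "pose_rank",
                                    "score_name", "value")],
                           idvar = c("compound_id", "isomer_id", "pose_rank"),
                           timevar = "score_name", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    sn <- unique(rows$score_name)
    wide <- wide[, c("compound_id", "isomer_id", "pose_rank", sn)]
    rows <- wide[order(rows_key <- paste(wide$compound_id, wide$isomer_id),
                       wide$pose_rank), , drop = FALSE]
    rownames(rows) <- NULL
  } else {
    sn <- setdiff(names(rows), c("compound_id", "isomer_id", "engine", "pose_rank"))
    rows$engine <- NULL
    key <- paste(rows$compound_id, rows$isomer_id, rows$pose_rank)
    dup <- duplicated(key)
    stopIfNot(!any(dup), sprintf("duplicate (compound, isomer, rank) keys: %s",
                                 paste(utils::head(unique(key[dup]), 5), collapse = "; ")))
  }
  stopIfNot(length(sn) > 0, "no scoring-function columns found")
  stopIfNot(!is.null(engine) && length(engine) == 1, "engine identifier required")
  # rank contiguity per (compound, isomer)
  grp <- split(rows$pose_rank, paste(rows$compound_id, rows$isomer_id, sep = "/"))
  badGrp <- names(grp)[!vapply(grp, function(r) all(sort(r) == seq_along(r)), logical(1))]
  stopIfNot(length(badGrp) == 0,
            sprintf("pose ranks not contiguous from 1 for: %s",
                    paste(utils::head(badGrp, 5), collapse = "; ")))
  stopIfNot(!anyNA(rows[, sn]), "missing score values in pose table")
  if (is.null(directions)) {
    directions <- stats::setNames(c("lower", rep("higher", length(sn) - 1)), sn)
  }
  methods::new("PoseScoreTable", engine = engine, scores = rows,
               scoreNames = sn, directions = directions[sn],
               nPoses = as.integer(max(rows$pose_rank, 0)))
}

# Shared finishing step: group-mean matrix -> engine-prefixed FeatureMatrix,
# with missing-compound accounting.
.finishAggregation <- function(agg, table, missing, compounds) {
  agg <- agg[order(rownames(agg)), , drop = FALSE]
  if (!is.null(compounds)) {
    lost <- setdiff(compounds, rownames(agg))
    if (length(lost)) {
      if (missing == "error")
        stopIfNot(FALSE, sprintf("compounds without poses: %s",
                                 paste(utils::head(lost, 5), collapse = ", ")))
      message(sprintf("%s: %d compound(s) have no poses and are dropped",
                      table@engine, length(lost)))
    }
  }
  colnames(agg) <- paste(table@engine, table@scoreNames, sep = ".")
  methods::new("FeatureMatrix", values = agg,
               provenance = rep("sb_score", ncol(agg)),
               metadata = list(engine = table@engine,
                               directions = stats::setNames(table@directions, colnames(agg))))
}

#' Best-pose structure-based features
#'
#' For every compound, takes the rank-1 (top-ranked by the engine's native
#' primary score) pose row of each stereoisomer and averages those rows
#' across isomers, column-wise. Single-isomer compounds pass their rank-1
#' row through unchanged. Column names are engine-prefixed. Ranking always
#' uses the stored `pose_rank` (the engine's native ordering), never a
#' rescoring column.
#'
#' @param table a [PoseScoreTable-class].
#' @param missing how to treat compounds absent from the table when
#'   `compounds` is given: `"drop"` (default, logged) or `"error"`.
#' @param compounds optional full compound roster used for missing-compound
#'   accounting.
#' @return A [FeatureMatrix-class] with one row per docked compound.
#' @export
bestPoseFeatures <- function(table, missing = c("drop", "error"), compounds = NULL) {
  methods::validObject(table)
  missing <- match.arg(missing)
  sc <- table@scores
  top <- sc$pose_rank == 1
  m <- as.matrix(sc[top, table@scoreNames, drop = FALSE])
  comp <- sc$compound_id[top]
  agg <- rowsum(m, comp) / as.vector(table(comp))
  .finishAggregation(agg, table, missing, compounds)
}

#' Binding-space average structure-based features
#'
#' For every compound, the column-wise mean over all poses of all
#' stereoisomers, pooled. With equal pose counts per isomer this equals the
#' mean of the per-isomer means.
#'
#' @inheritParams bestPoseFeatures
#' @return A [FeatureMatrix-class] with one row per docked compound.
#' @export
averagePoseFeatures <- function(table, missing = c("drop", "error"), compounds = NULL) {
  methods::validObject(table)
  missing <- match.arg(missing)
  sc <- table@scores
  m <- as.matrix(sc[, table@scoreNames, drop = FALSE])
  agg <- rowsum(m, sc$compound_id) / as.vector(table(sc$compound_id))
  .finishAggregation(agg, table, missing, compounds)
}

#' Assemble a multi-engine consensus feature block
#'
#' Column-wise concatenation of per-engine feature matrices (columns are
#' already engine-prefixed); compounds are restricted to the intersection of
#' all engines, so molecules undocked by any engine are excluded (logged).
#'
#' @param matrices list of two or more [FeatureMatrix-class] objects.
#' @return A [FeatureMatrix-class] over the compound intersection.
#' @export
assembleConsensusFeatures <- function(matrices) {
  stopIfNot(length(matrices) >= 2, "consensus assembly needs at least 2 engines")
  ids <- Reduce(intersect, lapply(matrices, compoundIds))
  stopIfNot(length(ids) > 0, "no compounds shared by all engines")
  dropped <- length(unique(unlist(lapply(matrices, compoundIds)))) - length(ids)
  if (dropped > 0)
    message(sprintf("consensus assembly: %d compound(s) not docked by all engines excluded", dropped))
  vals <- do.call(cbind, lapply(matrices, function(mm) featureValues(mm)[ids, , drop = FALSE]))
  stopIfNot(!anyDuplicated(colnames(vals)), "duplicate feature names across engines")
  methods::new("FeatureMatrix", values = vals,
               provenance = unlist(lapply(matrices, function(mm) mm@provenance), use.names = FALSE),
               metadata = list(engines = vapply(matrices, function(mm) mm@metadata$engine %||% NA_character_, "")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine feature matrices over shared compounds
#'
#' Row-aligned column concatenation of any feature matrices (e.g. the
#' selected ligand-based block plus a structure-based block), restricted to
#' the compound intersection.
#'
#' @param ... [FeatureMatrix-class] objects.
#' @return A [FeatureMatrix-class].
#' @export
combineFeatures <- function(...) {
  matrices <- list(...)
  stopIfNot(length(matrices) >= 1, "no feature matrices given")
  if (length(matrices) == 1) return(matrices[[1]])
  ids <- Reduce(intersect, lapply(matrices, compoundIds))
  stopIfNot(length(ids) > 0, "no shared compounds")
  vals <- do.call(cbind, lapply(matrices, function(mm) featureValues(mm)[ids, , drop = FALSE]))
  methods::new("FeatureMatrix", values = vals,
               provenance = unlist(lapply(matrices, function(mm) mm@provenance), use.names = FALSE),
               metadata = do.call(c, lapply(matrices, function(mm) mm@metadata)))
}

#' Subset a feature matrix by feature names or compounds
#'
#' @param x a [FeatureMatrix-class].
#' @param features feature names to keep (default all).
#' @param compounds compound ids to keep (default all).
#' @return A [FeatureMatrix-class].
#' @export
subsetFeatures <- function(x, features = NULL, compounds = NULL) {
  v <- featureValues(x); pr <- x@provenance
  if (!is.null(features)) {
    stopIfNot(all(features %in% colnames(v)),
              sprintf("unknown features: %s",
                      paste(utils::head(setdiff(features, colnames(v)), 5), collapse = ", ")))
    keep <- match(features, colnames(v))
    v <- v[, keep, drop = FALSE]; pr <- pr[keep]
  }
  if (!is.null(compounds)) {
    stopIfNot(all(compounds %in% rownames(v)), "unknown compound ids")
    v <- v[compounds, , drop = FALSE]
  }
  methods::new("FeatureMatrix", values = v, provenance = pr, metadata = x@metadata)
}

# ---- long-format pose-table I/O -------------------------------------------

#' Read / write pose tables as long-format delimited text
#'
#' Columns: `compound_id`, `isomer_id`, `engine`, `pose_rank`, `score_name`,
#' `value`.
#'
#' @param table a [PoseScoreTable-class].
#' @param file path.
#' @return `readPoseTable` returns a validated [PoseScoreTable-class].
#' @export
writePoseTable <- function(table, file) {
  sc <- table@scores
  long <- do.call(rbind, lapply(table@scoreNames, function(s) {
    data.frame(compound_id = sc$compound_id, isomer_id = sc$isomer_id,
               engine = table@engine, pose_rank = sc$pose_rank,
               score_name = s, value = sc[[s]], stringsAsFactors = FALSE)
  }))
  long <- long[order(long$compound_id, long$isomer_id, long$pose_rank), , drop = FALSE]
  utils::write.table(long, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writePoseTable
#' @export
readPoseTable <- function(file) {
  validatePoseTable(utils::read.delim(file, stringsAsFactors = FALSE))
}
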