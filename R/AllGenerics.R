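#' @rdname FeatureMatrix-class
#' @param object,x a `FeatureMatrix`.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname PoseScoreTable-class
#' @export
setGeneric("poseScores", function(x) standardGeneric("poseScores"))

#' @rdname PoseScoreTable-class
#' @export
setGeneric("scoreNames", function(x) standardGeneric("scoreNames"))

#' @rdname PoseScoreTable-class
#' @export
setGeneric("scoreDirections", function(x) standardGeneric("scoreDirections"))

#' @rdname PoseScoreTable-class
#' @export
setGeneric("engine", function(x) standardGeneric("engine"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

# ---- accessors -------------------------------------------------------------

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix-class
#' @export
setMethod("provenance", "FeatureMatrix", function(x) {
  stats::setNames(x@provenance, colnames(x@values))
})

#' @rdname FeatureMatrix-class
#' @export
setMethod("compoundIds", "FeatureMatrix", function(x) rownames(x@values))

#' @rdname FeatureMatrix-class
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

#' @rdname PoseScoreTable-class
#' @export
setMethod("poseScores", "PoseScoreTable", function(x) x@scores)

#' @rdname PoseScoreTable-class
#' @export
setMethod("scoreNames", "PoseScoreTable", function(x) x@scoreNames)

#' @rdname PoseScoreTable-class
#' @export
setMethod("scoreDirections", "PoseScoreTable", function(x) x@directions)

#' @rdname PoseScoreTable-class
#' @export
setMethod("engine", "PoseScoreTable", function(x) x@engine)

#' @rdname EvaluationReport-class
#' @export
setMethod("metrics", "EvaluationReport", function(x) x@metrics)

# ---- show methods ----------------------------------------------------------

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:", object@nCompounds, "compounds,",
      sprintf("binder fraction %.3f,", object@binderFraction),
      length(object@engines), "engine(s),", object@nPoses, "poses, seed",
      object@seed, "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@compounds), "compounds (",
      sum(object@compounds$label == "binder"), "binders ),",
      nrow(object@activities), "activity records,",
      length(object@poseTables), "pose table(s)\n")
})

setMethod("show", "PoseScoreTable", function(object) {
  cat("PoseScoreTable [", object@engine, "]:", nrow(object@scores), "pose rows,",
      length(unique(object@scores$compound_id)), "compounds,",
      length(object@scoreNames), "scoring functions\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  tab <- table(object@provenance)
  cat("FeatureMatrix:", nrow(object@values), "compounds x", ncol(object@values),
      "features (", paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (n =", object@n, "): TP", object@TP, "TN", object@TN,
      "FP", object@FP, "FN", object@FN, "\n  ")
  cat(paste(names(object@metrics), sprintf("%.3f", object@metrics), sep = "="),
      sep = "  ")
  cat("\n")
  if (length(object@flags)) cat("  zero-denominator conventions:",
                                paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ModelBundle", function(object) {
  cat("ModelBundle:", length(object@featureNames), "features,",
      object@spec$nTrees, "trees, seed", object@spec$seed, "\n")
})

setMethod("show", "ADReference", function(object) {
  cat("ADReference:", nrow(object@fingerprints), "training fingerprints,",
      length(object@featureNames), "descriptors; similarity Tc >",
      object@similarityCutoff, "; consensus", object@minMethods, "of 4\n")
})
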