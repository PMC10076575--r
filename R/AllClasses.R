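#' @import methods
NULL

# ---- GeneratorConfig -------------------------------------------------------

#' Configuration of the synthetic cohort generator
#'
#' Holds every knob of the synthetic data generator: cohort size and class
#' balance, the pK scale of the latent affinity, the class-conditional
#' lipophilicity/polarity effect sizes, and the pose-score noise model used to
#' emulate docking and rescoring output.
#'
#' @slot nCompounds number of compounds to generate.
#' @slot binderFraction target fraction of binders (pK >= threshold); the
#'   default 7303/12789 mirrors the class balance of a large curated hERG
#'   training collection.
#' @slot pkCenter centre of the emitted pK distribution (pK units); also the
#'   binder labelling threshold used downstream.
#' @slot pkSpread standard deviation of the emitted pK values (pK units).
#' @slot pkNoiseSd structure-independent noise added to the latent affinity,
#'   on the standardized affinity scale. At 0 the pK of a compound is an exact
#'   function of its structure.
#' @slot lipophilicityShift effect size by which binder logP exceeds
#'   non-binder logP (standardized descriptor units).
#' @slot polarityShift effect size by which binder TPSA is reduced.
#' @slot scaffoldEffectSd scale of the fixed chemotype (head-by-tail
#'   fragment) activity offsets; gives fingerprints similarity-dependent
#'   signal beyond bulk physicochemistry.
#' @slot nPoses docking poses generated per molecule per engine.
#' @slot engines engine identifiers; the identifier `"LiGen"` switches that
#'   engine to its extended descriptor mode (pharmacophore-distance block).
#' @slot nRescoring number of rescoring functions shared by all engines.
#' @slot nPharmacophoreDistances extra distance descriptors in LiGen mode
#'   (default 29, so that engine's feature total is 1 + 25 + 29 = 55).
#' @slot poseNoiseSd,compoundNoiseSd,engineBiasSd score-scale standard
#'   deviations of the pose-level, compound-level and engine-level noise
#'   components. Pose-level noise must exceed compound-level noise for
#'   averaging over poses to denoise.
#' @slot undockedFraction per-engine fraction of compounds that fail to dock.
#' @slot stereoisomerFraction fraction of compounds emitted as 2-isomer
#'   groups.
#' @slot seed integer seed; identical config + seed gives identical output.
#' @seealso [generatorConfig()], [generateCohort()]
#' @export
setClass("GeneratorConfig", representation(
  nCompounds = "integer", binderFraction = "numeric",
  pkCenter = "numeric", pkSpread = "numeric", pkNoiseSd = "numeric",
  lipophilicityShift = "numeric", polarityShift = "numeric",
  scaffoldEffectSd = "numeric",
  nPoses = "integer", engines = "character",
  nRescoring = "integer", nPharmacophoreDistances = "integer",
  poseNoiseSd = "numeric", compoundNoiseSd = "numeric", engineBiasSd = "numeric",
  undockedFraction = "numeric", stereoisomerFraction = "numeric",
  seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  errs <- character(0)
  chkFrac <- function(x, nm, openTop = TRUE) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || (openTop && x >= 1) || (!openTop && x > 1))
      sprintf("invalid config field '%s': must be a fraction in [0,1)", nm)
  }
  errs <- c(errs,
    if (object@nCompounds < 0) "invalid config field 'nCompounds': must be >= 0",
    if (object@binderFraction <= 0 || object@binderFraction >= 1)
      "invalid config field 'binderFraction': must lie in (0,1)",
    chkFrac(object@undockedFraction, "undockedFraction"),
    chkFrac(object@stereoisomerFraction, "stereoisomerFraction"),
    if (object@nPoses < 1) "invalid config field 'nPoses': must be >= 1",
    if (object@nRescoring < 1) "invalid config field 'nRescoring': must be >= 1",
    if (object@nPharmacophoreDistances < 0)
      "invalid config field 'nPharmacophoreDistances': must be >= 0",
    if (length(object@engines) < 1 || anyDuplicated(object@engines))
      "invalid config field 'engines': need at least one unique engine id")
  for (nm in c("pkSpread", "pkNoiseSd", "scaffoldEffectSd", "poseNoiseSd",
               "compoundNoiseSd", "engineBiasSd")) {
    v <- methods::slot(object, nm)
    if (length(v) != 1 || !is.finite(v) || v < 0)
      errs <- c(errs, sprintf("invalid config field '%s': must be a non-negative number", nm))
  }
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

# ---- SyntheticCohort -------------------------------------------------------

#' A generated compound cohort with optional pose-score tables
#'
#' @slot compounds data.frame with one row per compound: `compound_id`,
#'   `smiles`, `pK`, `label`, `n_isomers`.
#' @slot activities data.frame of raw activity measurements in
#'   activity-record layout (`compound_id`, `smiles`, `endpoint`, `relation`,
#'   `value`, `unit`), possibly several rows per compound including censored
#'   extras.
#' @slot poseTables named list of [PoseScoreTable-class] objects, one per
#'   engine.
#' @slot truth data.frame of latent generator state per compound (`affinity`,
#'   descriptor contributions, emitted pK).
#' @slot params list of the generator parameters used.
#' @export
setClass("SyntheticCohort", representation(
  compounds = "data.frame", activities = "data.frame",
  poseTables = "list", truth = "data.frame", params = "list"))

# ---- PoseScoreTable --------------------------------------------------------

#' Multi-pose docking score table for one engine
#'
#' Wide layout: one row per (compound, isomer, pose rank), key columns
#' `compound_id`, `isomer_id`, `pose_rank`, followed by the named scoring
#' function columns. Rank 1 carries the best primary score under the engine's
#' native convention.
#'
#' @slot engine engine identifier.
#' @slot scores data.frame as described above.
#' @slot scoreNames scoring-function column names (first is the primary).
#' @slot directions named character vector, `"lower"`/`"higher"` is better,
#'   per scoring function; carried as metadata and never used to flip values.
#' @slot nPoses declared number of poses per (compound, isomer).
#' @export
setClass("PoseScoreTable", representation(
  engine = "character", scores = "data.frame", scoreNames = "character",
  directions = "character", nPoses = "integer"))

setValidity("PoseScoreTable", function(object) {
  sc <- object@scores
  need <- c("compound_id", "isomer_id", "pose_rank")
  if (!all(need %in% names(sc))) return("scores must contain compound_id, isomer_id, pose_rank")
  if (!all(object@scoreNames %in% names(sc))) return("missing scoring-function columns")
  key <- paste(sc$compound_id, sc$isomer_id, sc$pose_rank)
  if (anyDuplicated(key)) return("duplicate (compound, isomer, pose_rank) keys")
  TRUE
})

# ---- FeatureMatrix ---------------------------------------------------------

#' Compounds-by-features matrix with column provenance
#'
#' @slot values numeric matrix, rownames are compound identifiers, colnames
#'   are unique feature names.
#' @slot provenance character vector parallel to the columns, each one of
#'   `"lb_physchem"`, `"lb_fp"`, `"sb_score"`.
#' @slot metadata free-form list (fingerprint parameters, engine dictionary).
#' @export
setClass("FeatureMatrix", representation(
  values = "matrix", provenance = "character", metadata = "list"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  if (is.null(colnames(v)) || anyDuplicated(colnames(v))) return("column names must be unique")
  if (is.null(rownames(v))) return("rownames (compound ids) required")
  if (length(object@provenance) != ncol(v)) return("provenance length must equal ncol")
  if (!all(object@provenance %in% c("lb_physchem", "lb_fp", "sb_score")))
    return("provenance tags must be lb_physchem, lb_fp or sb_score")
  if (anyNA(v)) return("feature matrix must not contain missing values")
  TRUE
})

# ---- EvaluationReport ------------------------------------------------------

#' Binary classification evaluation report
#'
#' Confusion counts with the binder class as positive, plus MCC, accuracy,
#' AUC, precision, sensitivity and specificity.
#'
#' @slot TP,TN,FP,FN confusion counts.
#' @slot metrics named numeric vector (MCC, ACC, AUC, precision, SE, SP; AUC
#'   is NA when probabilities were not supplied).
#' @slot n number of evaluated compounds.
#' @slot flags character vector naming metrics that hit a zero-denominator
#'   convention.
#' @export
setClass("EvaluationReport", representation(
  TP = "integer", TN = "integer", FP = "integer", FN = "integer",
  metrics = "numeric", n = "integer", flags = "character"))

setValidity("EvaluationReport", function(object) {
  if (object@TP + object@TN + object@FP + object@FN != object@n)
    return("counts must sum to n")
  if (any(c(object@TP, object@TN, object@FP, object@FN) < 0))
    return("counts must be non-negative")
  TRUE
})

# ---- ADReference -----------------------------------------------------------

#' Fitted applicability-domain reference
#'
#' Stores everything the four domain methods need: the training fingerprints
#' (similarity method), the PCA model with the component-1/2 training ranges
#' (range method), the standardized-space centroid distance threshold
#' (Euclidean method) and the kernel density model with its coverage cutoff
#' (density method), plus the consensus configuration.
#'
#' @export
setClass("ADReference", representation(
  fingerprints = "matrix", center = "numeric", scale = "numeric",
  rotation = "matrix", pcRange = "matrix",
  distanceThreshold = "numeric", densityCutoff = "numeric",
  densityTrain = "matrix", bandwidth = "numeric",
  similarityCutoff = "numeric", distancePercentile = "numeric",
  densityCoverage = "numeric", minMethods = "integer",
  featureNames = "character"))

# ---- ModelBundle -----------------------------------------------------------

#' Trained classifier plus everything needed to apply it safely
#'
#' @slot fit the fitted ranger random forest.
#' @slot featureNames,provenance the exact training feature schema;
#'   prediction refuses inputs whose columns do not match.
#' @slot fingerprints training ECFP fingerprints (for the applicability
#'   domain similarity method and diversity splitting); may have zero rows.
#' @slot adRef fitted [ADReference-class] (or NULL).
#' @slot spec list of model settings (nTrees, maxDepth, seed, positiveClass).
#' @export
setClass("ModelBundle", representation(
  fit = "ANY", featureNames = "character", provenance = "character",
  fingerprints = "matrix", adRef = "ANY", spec = "list"))
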