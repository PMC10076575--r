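# Config-driven experiment runner tying the stages together: curation,
# featurization (ligand-based, structure-based best-pose / average, and
# their combinations), feature selection, training, ten-fold
# cross-validation, external validation, applicability domain and the
# similarity-accuracy trend. Every run writes its outputs plus a manifest
# under a fresh directory, and all randomness flows from one top-level seed
# expanded per stage.

.FEATURE_MODES <- c("lb", "sb_bp", "sb_av", "lb+sb_bp", "lb+sb_av")

#' Assemble a pipeline configuration
#'
#' @param mode feature mode: `"lb"` (selected ligand-based descriptors),
#'   `"sb_bp"` / `"sb_av"` (multi-engine consensus of best-pose / average
#'   scores), or `"lb+sb_bp"` / `"lb+sb_av"` (selected LB block plus the SB
#'   block).
#' @param generator a [GeneratorConfig-class] describing the simulated
#'   cohort (stands in for the activity/pose input paths of a real run).
#' @param activityFile,poseFiles optional paths to a delimited activity
#'   table and named long-format pose tables; when given they replace the
#'   generator as input source.
#' @param externalDissimilarity dissimilarity of the simulated external set.
#' @param nExternal external-set size.
#' @param model settings from [modelSpec()].
#' @param threshold binder labelling threshold (pK units).
#' @param outputDir run directory (created; must not pre-exist).
#' @param seed top-level seed.
#' @return list of class `hergml_pipeline_config`.
#' @export
pipelineConfig <- function(mode = "lb",
                           generator = generatorConfig(),
                           activityFile = NULL, poseFiles = NULL,
                           externalDissimilarity = "medium",
                           nExternal = 320L,
                           model = modelSpec(),
                           threshold = 5.0,
                           outputDir = tempfile("hergml_run_"),
                           seed = 1L) {
  stopIfNot(mode %in% .FEATURE_MODES,
            sprintf("mode must be one of: %s", paste(.FEATURE_MODES, collapse = ", ")))
  structure(list(mode = mode, generator = generator,
                 activityFile = activityFile, poseFiles = poseFiles,
                 externalDissimilarity = externalDissimilarity,
                 nExternal = as.integer(nExternal), model = model,
                 threshold = threshold, outputDir = outputDir,
                 seed = as.integer(seed)),
            class = "hergml_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipelineConfig()] arguments; the
#' `generator:` and `model:` blocks onto [generatorConfig()] and
#' [modelSpec()].
#'
#' @param file YAML path.
#' @return A pipeline configuration list.
#' @export
readPipelineConfig <- function(file) {
  y <- yaml::read_yaml(file)
  gen <- do.call(generatorConfig, y$generator %||% list())
  mod <- do.call(modelSpec, y$model %||% list())
  args <- y[setdiff(names(y), c("generator", "model"))]
  do.call(pipelineConfig, c(args, list(generator = gen, model = mod)))
}

# Build the feature matrix for a cohort under a mode; `selected` carries the
# LB feature names chosen on the training data (NULL = select here).
.featuresForMode <- function(mode, compounds, poseTables, selected = NULL,
                             labels = NULL) {
  lbPart <- sbPart <- NULL
  if (grepl("lb", mode, fixed = TRUE)) {
    lb <- computeLBFeatures(compounds$smiles, ids = compounds$compound_id)
    if (is.null(selected)) {
      stopIfNot(!is.null(labels), "labels needed to select LB features")
      lab <- labels[match(compoundIds(lb), compounds$compound_id)]
      selected <- bestFirstSelect(lb, lab)
      if (length(selected) == 0) selected <- .PHYSCHEM_NAMES
    }
    lbPart <- subsetFeatures(lb, features = selected)
  }
  if (grepl("sb", mode, fixed = TRUE)) {
    agg <- if (grepl("bp", mode, fixed = TRUE)) bestPoseFeatures else averagePoseFeatures
    mats <- lapply(poseTables, agg)
    sbPart <- if (length(mats) > 1) assembleConsensusFeatures(mats) else mats[[1]]
  }
  feat <- if (!is.null(lbPart) && !is.null(sbPart)) combineFeatures(lbPart, sbPart)
          else lbPart %||% sbPart
  list(features = feat, selected = selected)
}

#' Run a full experiment
#'
#' Simulates (or reads) the training inputs, curates them, builds the
#' configured feature assembly, selects ligand-based features where the mode
#' includes them, trains the classifier, and evaluates by stratified
#' ten-fold cross-validation and on an external set of configured
#' dissimilarity, including applicability-domain verdicts and the
#' accuracy-versus-similarity trend. All tables and a run manifest are
#' written to `config$outputDir`.
#'
#' @param config from [pipelineConfig()] or [readPipelineConfig()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the trained `bundle`, `cvReport`,
#'   `externalReport`, `adVerdicts`, `trend`, `selected` features and the
#'   output directory.
#' @export
runExperiment <- function(config, quiet = FALSE) {
  say <- if (quiet) function(...) invisible() else function(...) message(...)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  gen <- config$generator
  gen@seed <- deriveSeed(config$seed, 1L)

  say("stage 1/6: cohort")
  needPoses <- grepl("sb", config$mode, fixed = TRUE)
  cohort <- generateCohort(gen, poses = needPoses)
  writeActivityTable(cohort@activities, file.path(config$outputDir, "activities.tsv"))

  say("stage 2/6: curation")
  curated <- curateActivities(cohort@activities, threshold = config$threshold)
  writeActivityTable(curated, file.path(config$outputDir, "curated.tsv"))
  # modelling roster: one representative compound per curated structure
  std <- standardizeStructure(cohort@compounds$smiles)
  keep <- !duplicated(std) & !is.na(std)
  compounds <- cohort@compounds[keep, , drop = FALSE]
  cur <- curated[match(std[keep], curated$canonical_smiles), , drop = FALSE]
  compounds$pK <- cur$pK
  compounds$label <- cur$label
  poseTables <- if (needPoses) {
    lapply(cohort@poseTables, function(pt) {
      sc <- pt@scores[pt@scores$compound_id %in% compounds$compound_id, , drop = FALSE]
      methods::initialize(pt, scores = sc)
    })
  } else list()

  say("stage 3/6: features (+ selection)")
  built <- .featuresForMode(config$mode, compounds, poseTables,
                            labels = compounds$label)
  feat <- built$features
  if (!is.null(built$selected))
    writeLines(built$selected, file.path(config$outputDir, "selected_features.txt"))
  writeFeatureMatrix(feat, file.path(config$outputDir, "features.tsv"))
  ids <- compoundIds(feat)
  labels <- compounds$label[match(ids, compounds$compound_id)]
  fps <- fingerprintMatrix(compounds$smiles[match(ids, compounds$compound_id)], ids)

  say("stage 4/6: cross-validation + final model")
  spec <- config$model
  spec$seed <- deriveSeed(config$seed, 2L)
  cvRep <- crossValidate(feat, labels, spec)
  writeReport(cvRep, file.path(config$outputDir, "cv_report.tsv"))
  adRef <- adReference(feat, fps)
  bundle <- trainClassifier(feat, labels, spec, fingerprints = fps, adRef = adRef)

  say("stage 5/6: external validation")
  extGen <- gen
  extGen@nCompounds <- config$nExternal
  extGen@seed <- deriveSeed(config$seed, 3L)
  external <- generateExternalSet(extGen, config$externalDissimilarity,
                                  poses = needPoses)
  extBuilt <- .featuresForMode(config$mode, external@compounds,
                               external@poseTables, selected = built$selected)
  extFeat <- extBuilt$features
  extIds <- compoundIds(extFeat)
  extTruth <- external@compounds$label[match(extIds, external@compounds$compound_id)]
  extPred <- predict(bundle, extFeat)
  extRep <- evaluationReport(extTruth, extPred$label, extPred$probability)
  writeReport(extRep, file.path(config$outputDir, "external_report.tsv"))

  say("stage 6/6: applicability domain + trend")
  extFps <- fingerprintMatrix(
    external@compounds$smiles[match(extIds, external@compounds$compound_id)], extIds)
  verdicts <- assessAD(extFeat, extFps, adRef)
  utils::write.table(verdicts, file.path(config$outputDir, "ad_verdicts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  trend <- trendReport(verdicts$nearest_neighbor_tc, extTruth, extPred$label)
  utils::write.table(trend, file.path(config$outputDir, "trend.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  manifest <- list(mode = config$mode, seed = config$seed,
                   threshold = config$threshold,
                   generator = .configAsList(gen),
                   model = spec,
                   externalDissimilarity = config$externalDissimilarity,
                   nExternal = config$nExternal,
                   nCurated = nrow(curated),
                   nSelected = length(built$selected %||% character(0)),
                   package = as.character(utils::packageVersion("hergml")),
                   rversion = R.version.string)
  jsonlite::write_json(manifest, file.path(config$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(bundle = bundle, cvReport = cvRep, externalReport = extRep,
                 adVerdicts = verdicts, trend = trend,
                 selected = built$selected, outputDir = config$outputDir,
                 cohort = cohort, external = external))
}

.configAsList <- function(config) {
  nms <- methods::slotNames(methods::is(config)[1])
  stats::setNames(lapply(nms, function(s) methods::slot(config, s)), nms)
}
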