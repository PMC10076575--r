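# Feature-matrix persistence: values as tab-delimited text plus a JSON
# sidecar recording column names, provenance tags and fingerprint metadata.

#' Write / read a feature matrix with its schema sidecar
#'
#' `writeFeatureMatrix` writes `<file>` (TSV, compounds in rows) and
#' `<file>.schema.json`; `readFeatureMatrix` reads both back and restores
#' the typed object.
#'
#' @param x a [FeatureMatrix-class].
#' @param file path of the TSV file.
#' @return `readFeatureMatrix` returns a [FeatureMatrix-class].
#' @export
writeFeatureMatrix <- function(x, file) {
  v <- featureValues(x)
  df <- data.frame(compound_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  schema <- list(columns = colnames(v), provenance = unname(x@provenance),
                 metadata = x@metadata)
  jsonlite::write_json(schema, paste0(file, ".schema.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  schema <- jsonlite::read_json(paste0(file, ".schema.json"), simplifyVector = TRUE)
  v <- as.matrix(df[, schema$columns, drop = FALSE])
  rownames(v) <- df$compound_id
  md <- schema$metadata
  methods::new("FeatureMatrix", values = v, provenance = schema$provenance,
               metadata = if (is.list(md)) md else list())
}

#' Export cohort structures as an SD file
#'
#' @param cohort a [SyntheticCohort-class].
#' @param file output SDF path.
#' @export
exportSDF <- function(cohort, file) {
  mols <- .parseMols(cohort@compounds$smiles)
  ok <- !vapply(mols, is.null, logical(1))
  sdf <- methods::new("SDFset", SDF = mols[ok],
                      ID = cohort@compounds$compound_id[ok])
  ChemmineR::write.SDF(sdf, file, cid = TRUE)
  invisible(file)
}
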