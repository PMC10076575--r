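# Curation: raw activity records -> one labelled record per unique
# standardized structure. Measurements are converted to pK (negative log
# molar), censored values are excluded, structures are standardized, and
# duplicate measurements are collapsed to their median.

.ENDPOINTS <- c("IC50", "EC50", "Ki", "Kd")
.UNIT_FACTORS <- c("M" = 1, "mM" = 1e-3, "uM" = 1e-6, "µM" = 1e-6, "nM" = 1e-9)

#' Convert an activity value to pK
#'
#' pK is the negative base-10 logarithm of the molar concentration, so
#' 10 uM corresponds to pK 5 (the conventional hit threshold in HTS
#' campaigns and the binder labelling threshold used here).
#'
#' @param value positive numeric activity value(s).
#' @param unit concentration unit, one of `"M"`, `"mM"`, `"uM"` (or the
#'   micro-sign spelling), `"nM"`; recycled against `value`.
#' @return Numeric vector of pK values.
#' @examples
#' toPK(10, "uM")   # 5
#' toPK(100, "nM")  # 7
#' @export
toPK <- function(value, unit) {
  stopIfNot(all(is.finite(value)) && all(value > 0),
            "activity values must be positive finite numbers")
  f <- .UNIT_FACTORS[as.character(unit)]
  stopIfNot(!anyNA(f), sprintf("unknown unit(s): %s",
                               paste(unique(unit[is.na(f)]), collapse = ", ")))
  -log10(value * unname(f))
}

#' Drop censored activity records
#'
#' Records whose relation qualifier is `>` or `<` carry only a bound on the
#' activity and are excluded; only exact (`=`) measurements survive. Order is
#' preserved.
#'
#' @param records data.frame with a `relation` column.
#' @return The subset of `records` with `relation == "="`.
#' @export
filterCensored <- function(records) {
  stopIfNot("relation" %in% names(records), "records need a 'relation' column")
  records[records$relation == "=", , drop = FALSE]
}

#' Label a compound from its pK
#'
#' Binder iff pK >= threshold; the boundary is inclusive on the binder side.
#'
#' @param pK finite numeric pK value(s).
#' @param threshold labelling threshold (default 5.0, i.e. 10 uM).
#' @return Character vector, `"binder"` or `"non-binder"`.
#' @examples
#' labelCompound(c(5, 4.99, 7.2))
#' @export
labelCompound <- function(pK, threshold = 5.0) {
  stopIfNot(all(is.finite(pK)), "pK must be finite")
  ifelse(pK >= threshold, "binder", "non-binder")
}

#' Aggregate duplicate measurements of one structure
#'
#' Computes the median pK over all measurements of a structure, pooled
#' across endpoint types, and records the number of measurements.
#'
#' @param pKs numeric vector of per-record pK values for one structure.
#' @return list with `pK` (median) and `n_measurements`.
#' @export
aggregateDuplicates <- function(pKs) {
  stopIfNot(length(pKs) > 0, "cannot aggregate an empty measurement group")
  list(pK = stats::median(pKs), n_measurements = length(pKs))
}

#' Curate a raw activity table to labelled unique structures
#'
#' Applies the full curation sequence: endpoint vocabulary check, censored
#' value exclusion, unit conversion to pK, structure standardization
#' (salt removal, neutralization, canonicalization), duplicate collapse by
#' median pK, and binder labelling. Records with unparseable structures are
#' dropped with a message. When `target`/`organism` columns are present the
#' table is first filtered on the requested values (upstream source
#' selection).
#'
#' @param records data.frame with columns `compound_id`, `smiles`,
#'   `endpoint`, `relation`, `value`, `unit` (optionally `target`,
#'   `organism`).
#' @param threshold binder labelling threshold in pK units.
#' @param target,organism optional exact-match filters applied when the
#'   corresponding column exists.
#' @return data.frame with one row per unique canonical structure:
#'   `canonical_smiles`, `pK`, `label`, `n_measurements`.
#' @export
curateActivities <- function(records, threshold = 5.0,
                             target = NULL, organism = NULL) {
  need <- c("compound_id", "smiles", "endpoint", "relation", "value", "unit")
  stopIfNot(all(need %in% names(records)),
            paste("activity table needs columns:", paste(need, collapse = ", ")))
  if (!is.null(target) && "target" %in% names(records))
    records <- records[records$target %in% target, , drop = FALSE]
  if (!is.null(organism) && "organism" %in% names(records))
    records <- records[records$organism %in% organism, , drop = FALSE]
  records <- records[records$endpoint %in% .ENDPOINTS, , drop = FALSE]
  records <- filterCensored(records)
  if (nrow(records) == 0) {
    return(data.frame(canonical_smiles = character(0), pK = numeric(0),
                      label = character(0), n_measurements = integer(0),
                      stringsAsFactors = FALSE))
  }
  records$pK <- toPK(records$value, records$unit)
  canon <- standardizeStructure(records$smiles)
  bad <- is.na(canon)
  if (any(bad)) {
    message(sprintf("dropping %d record(s) with unparseable structures", sum(bad)))
    records <- records[!bad, , drop = FALSE]
    canon <- canon[!bad]
  }
  groups <- split(records$pK, canon)
  agg <- lapply(groups, aggregateDuplicates)
  out <- data.frame(canonical_smiles = names(groups),
                    pK = vapply(agg, `[[`, 0, "pK"),
                    n_measurements = vapply(agg, function(a) as.integer(a$n_measurements), 0L),
                    stringsAsFactors = FALSE)
  out$label <- labelCompound(out$pK, threshold)
  rownames(out) <- NULL
  out[, c("canonical_smiles", "pK", "label", "n_measurements")]
}

# ---- delimited-text I/O ----------------------------------------------------

#' Read / write activity and curated tables as delimited text
#'
#' Plain tab-separated text with a header row.
#'
#' @param file path.
#' @param records data.frame to write.
#' @return `readActivityTable` returns a data.frame.
#' @export
readActivityTable <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname readActivityTable
#' @export
writeActivityTable <- function(records, file) {
  utils::write.table(records, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
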