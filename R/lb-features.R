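# Ligand-based feature block: 11 physicochemical descriptors plus two
# 1024-bit hashed circular fingerprint blocks (element-invariant "ECFP6" and
# functional-class "FCFP6", diameter-6 convention), 2059 features in total.
# Also fingerprint similarity and chemical-space summaries (PCA, Murcko
# scaffolds).

#' The ligand-based feature schema
#'
#' @return list with `physchem_names` (11 descriptor names), `fp_bits`
#'   (bits per fingerprint block), and `total` (2059).
#' @export
lbFeatureSchema <- function() {
  list(physchem_names = .PHYSCHEM_NAMES, fp_bits = 1024L,
       fp_blocks = c("ECFP6", "FCFP6"),
       total = length(.PHYSCHEM_NAMES) + 2L * 1024L)
}

#' Compute the ligand-based feature matrix
#'
#' One row per compound; columns are the 11 physicochemical descriptors
#' (tagged `lb_physchem`) followed by 1024 ECFP6 bits and 1024 FCFP6 bits
#' (tagged `lb_fp`). Rows whose structure cannot be parsed are skipped with a
#' message. Deterministic and independent of input order.
#'
#' @param smiles character vector of (standardized) SMILES.
#' @param ids compound identifiers used as rownames (default: `names(smiles)`
#'   or the SMILES themselves).
#' @return A [FeatureMatrix-class] with 2059 columns.
#' @export
computeLBFeatures <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else smiles
  stopIfNot(length(ids) == length(smiles), "ids must parallel smiles")
  stopIfNot(!anyDuplicated(ids), "compound ids must be unique")
  pc <- .physchem(smiles)
  e6 <- .ecfp(smiles, 1024L)
  f6 <- .fcfp(smiles, 1024L)
  vals <- cbind(pc, e6, f6)
  colnames(vals) <- c(.PHYSCHEM_NAMES,
                      sprintf("ECFP6_%04d", seq_len(1024L)),
                      sprintf("FCFP6_%04d", seq_len(1024L)))
  rownames(vals) <- ids
  ok <- stats::complete.cases(vals)
  if (any(!ok)) {
    message(sprintf("skipping %d compound(s) with unparseable structures: %s",
                    sum(!ok), paste(utils::head(ids[!ok], 5), collapse = ", ")))
  }
  methods::new("FeatureMatrix", values = vals[ok, , drop = FALSE],
               provenance = c(rep("lb_physchem", length(.PHYSCHEM_NAMES)),
                              rep("lb_fp", 2048L)),
               metadata = list(fingerprint = list(type = c("ECFP6", "FCFP6"),
                                                  bits = 1024L, radius = 3L)))
}

#' Compute an ECFP6 fingerprint matrix
#'
#' Convenience accessor for the 1024-bit ECFP6 block alone (used by the
#' applicability-domain similarity method and diversity splitting).
#'
#' @inheritParams computeLBFeatures
#' @return Integer 0/1 matrix with one row per compound.
#' @export
fingerprintMatrix <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else smiles
  fp <- .ecfp(smiles, 1024L)
  rownames(fp) <- ids
  fp[stats::complete.cases(fp), , drop = FALSE]
}

#' Tanimoto similarity between bit vectors
#'
#' |a AND b| / |a OR b|, defined as 1 when both vectors are all-zero (two
#' featureless structures are treated as identical).
#'
#' @param a,b equal-length 0/1 vectors.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimoto <- function(a, b) {
  stopIfNot(length(a) == length(b), "fingerprints must have equal length")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# Rowwise max Tanimoto of each query fingerprint against a reference matrix;
# returns the nearest-neighbour similarity per query row.
.nearestTanimoto <- function(query, ref) {
  stopIfNot(ncol(query) == ncol(ref), "fingerprints must have equal length")
  q <- query %*% t(ref)                        # intersection counts
  nq <- rowSums(query); nr <- rowSums(ref)
  un <- outer(nq, nr, "+") - q                 # union counts
  tc <- ifelse(un == 0, 1, q / pmax(un, 1))
  apply(tc, 1, max)
}

#' Murcko scaffold frequency summary
#'
#' Strips side chains to the molecular framework (ring systems plus the
#' linkers between them) and tabulates scaffold frequency together with the
#' mean and standard deviation of pK in each scaffold group. Acyclic
#' molecules are grouped under an explicit `"no-scaffold"` row. Rows are
#' sorted by descending count.
#'
#' @param smiles character vector of structures.
#' @param pK parallel numeric vector of pK values.
#' @return data.frame with columns `scaffold`, `count`, `mean_pK`, `sd_pK`
#'   (sd 0 for singleton groups).
#' @export
murckoScaffoldSummary <- function(smiles, pK) {
  stopIfNot(length(smiles) == length(pK), "smiles and pK must be parallel")
  scaf <- .murckoScaffold(smiles)
  scaf[is.na(scaf)] <- "no-scaffold"
  groups <- split(pK, scaf)
  out <- data.frame(scaffold = names(groups),
                    count = lengths(groups),
                    mean_pK = vapply(groups, mean, 0),
                    sd_pK = vapply(groups, function(g) if (length(g) > 1) stats::sd(g) else 0, 0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$scaffold), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The extended chemical-space descriptor set
#'
#' The 11 core physicochemical descriptors plus 15 additional standard
#' 2-D descriptors (ring, aromaticity, heteroatom and functional-group
#' counts, molar refractivity). This 26-descriptor set is the package's own
#' stand-in for an unspecified commercial descriptor panel and is used for
#' chemical-space PCA.
#'
#' @param smiles character vector of structures.
#' @return Numeric matrix with 26 named columns.
#' @export
chemspaceDescriptors <- function(smiles) {
  .physchem(smiles, extended = TRUE)
}

#' Chemical-space principal component analysis
#'
#' Standardizes each descriptor to zero mean and unit variance, drops
#' constant columns with a warning, performs PCA and returns the first two
#' components with their explained-variance fractions. The sign of each
#' returned component is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param descriptors numeric matrix (compounds x descriptors), e.g. from
#'   [chemspaceDescriptors()].
#' @param nComponents number of components to return (default 2).
#' @return list with `scores`, `loadings`, `explained_variance` (fractions,
#'   full spectrum) and `kept` (descriptor names used).
#' @export
chemspacePCA <- function(descriptors, nComponents = 2L) {
  x <- as.matrix(descriptors)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  stopIfNot(nrow(x) >= 3, "chemical-space PCA needs at least 3 compounds")
  sds <- apply(x, 2, stats::sd)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    warning(sprintf("dropping %d constant descriptor(s): %s", sum(const),
                    paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(nComponents, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  sco <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sign(rot[which.max(abs(rot[, j])), j])
    if (s < 0) { rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j] }
  }
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = sco, loadings = rot, explained_variance = ev,
       kept = colnames(x))
}
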