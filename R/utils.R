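# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so seeded package
#' operations never disturb the user's random stream.
#' @noRd
withSeed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage seed from a top-level seed; kept well below .Machine$integer.max.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 31L + as.numeric(offset)) %% 2147483587)
}

#' @noRd
stopIfNot <- function(cond, msg, class = "hergml_error") {
  if (!isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(TRUE)
}

# Column standardization that tolerates constant columns (returned as zeros).
standardizeColumns <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
  }
  scale[!is.finite(scale) | scale == 0] <- 1
  out <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

# Pearson correlation with the convention that a constant vector has
# correlation 0 (used throughout feature selection).
safeCor <- function(x, y) {
  r <- suppressWarnings(stats::cor(x, y))
  r[!is.finite(r)] <- 0
  r
}
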