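# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a base seed
#'
#' Stage toggling must not shift another stage's randomness, so every stage
#' draws from its own named substream derived deterministically from one base
#' seed. Result always fits in a 32-bit integer.
#'
#' @param seed base integer seed.
#' @param stream character stream name.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # small rolling-polynomial hash of the stream name, folded into the seed
  h <- 0
  for (cp in utf8ToInt(stream)) h <- (h * 131 + cp) %% 2147483629
  as.integer((abs(seed) + h) %% 2147483629 + 1)
}

# sum-to-one check used by persona mixes and marginal targets
assert_proportions <- function(p, what, tol = 1e-9) {
  if (any(p < -tol)) stop(what, " has negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

# symmetric PSD check for trait correlation matrices
assert_psd <- function(m, what, tol = 1e-8) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop(what, " must be symmetric", call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) stop(what, " is not positive semi-definite", call. = FALSE)
  invisible(TRUE)
}

# draw one category per row from per-row probability matrix (vectorised)
sample_categories <- function(prob, categories) {
  cum <- t(apply(prob, 1L, cumsum))
  u <- stats::runif(nrow(prob)) * cum[, ncol(cum)]
  idx <- rowSums(u > cum) + 1L
  categories[idx]
}

#' Write a result object to JSON
#'
#' Thin wrapper with the conventions used throughout the package: unboxed
#' scalars, full numeric precision, readable indentation.
#'
#' @param x list to serialise.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(strip_classes(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# recursively drop S3 classes from plain-list result objects so any report
# component serialises; data frames are kept as-is
strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}
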