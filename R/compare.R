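#' Standardize scale scores to a T-score metric
#'
#' `T = 50 + 10 * (x - mean(ref)) / sd(ref)`, so the reference sample has
#' mean 50 and SD 10. The reference here is whatever sample the analysis
#' designates (for this package, a synthetic reference cohort — not an
#' official item-calibration lookup), and T-scores are invariant to any
#' common affine transform of `x` and the reference.
#'
#' @param x scores to standardize.
#' @param reference reference-sample scores (at least 2 distinct values).
#' @return Numeric T-scores.
#' @export
tscore_standardize <- function(x, reference) {
  s <- stats::sd(reference, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    stop("reference must have at least 2 distinct values", call. = FALSE)
  }
  50 + 10 * (x - mean(reference, na.rm = TRUE)) / s
}

#' Flag a difference exceeding the small-effect T-score threshold
#'
#' Strict inequality: a difference of exactly `threshold` T-score points is
#' not flagged. Symmetric in its arguments.
#'
#' @param t1,t2 T-scores on a common metric.
#' @param threshold flagging threshold, default 2 ("small" effect).
#' @return Logical.
#' @export
effect_flag <- function(t1, t2, threshold = 2) {
  abs(t1 - t2) > threshold
}

#' Pairwise-complete correlation matrix with Fisher-z confidence intervals
#'
#' Pearson (default) or Spearman correlations over all pairs of columns,
#' pairwise-complete, with 95% (by default) confidence intervals from the
#' Fisher z transform: `z = atanh(r) +/- z_crit / sqrt(n - 3)`. Cells with a
#' constant column or fewer than 3 complete pairs are `NA`.
#'
#' @param data data.frame or matrix of numeric variables.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param conf_level confidence level, default 0.95.
#' @return A list of class `qc_cormat`: matrices `r`, `lower`, `upper`, `n`.
#' @export
correlation_matrix <- function(data, method = "pearson", conf_level = 0.95) {
  m <- as.matrix(data)
  method <- match.arg(method, c("pearson", "spearman"))
  p <- ncol(m)
  n_mat <- crossprod(!is.na(m))
  r <- suppressWarnings(
    stats::cor(m, use = "pairwise.complete.obs", method = method))
  r[n_mat < 3L] <- NA_real_
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- 1 / sqrt(pmax(n_mat - 3, 1))
  z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
  lower <- tanh(z - zc * se)
  upper <- tanh(z + zc * se)
  diag(lower) <- diag(upper) <- 1
  structure(list(r = r, lower = lower, upper = upper, n = n_mat,
                 method = method, conf_level = conf_level),
            class = "qc_cormat")
}

#' Compare two correlation matrices over the same variable pairs
#'
#' Elementwise comparison over the lower triangle (diagonal excluded):
#' mean and maximum absolute difference, the share of pairs whose absolute
#' difference exceeds each threshold, sign flips (opposite nonzero signs),
#' and the share of pairs where the second matrix's coefficient is larger in
#' absolute value.
#'
#' @param m1,m2 `qc_cormat` objects or plain correlation matrices with
#'   identical variable sets.
#' @param thresholds absolute-difference thresholds to tabulate.
#' @return A list of class `qc_corcmp`: `n_pairs`, `mean_abs_diff`,
#'   `max_abs_diff`, `prop_exceeding` (named by threshold), `n_sign_flips`,
#'   `sign_flips` (data.frame), `share_m2_larger`.
#' @export
compare_correlation_matrices <- function(m1, m2,
                                         thresholds = c(0.05, 0.10, 0.15,
                                                        0.20)) {
  r1 <- if (inherits(m1, "qc_cormat")) m1$r else as.matrix(m1)
  r2 <- if (inherits(m2, "qc_cormat")) m2$r else as.matrix(m2)
  if (!identical(dim(r1), dim(r2))) stop("matrices differ in dimension")
  if (!is.null(colnames(r1)) && !is.null(colnames(r2))) {
    if (!setequal(colnames(r1), colnames(r2))) {
      stop("variable sets differ", call. = FALSE)
    }
    r2 <- r2[rownames(r1), colnames(r1)]
  }
  lt <- lower.tri(r1)
  a <- r1[lt]; b <- r2[lt]
  pair_idx <- which(lt, arr.ind = TRUE)
  d <- abs(a - b)
  flips <- sign(a) * sign(b) < 0
  flip_df <- data.frame(
    var_a = colnames(r1)[pair_idx[flips, 2L]] %||% pair_idx[flips, 2L],
    var_b = rownames(r1)[pair_idx[flips, 1L]] %||% pair_idx[flips, 1L],
    r1 = a[flips], r2 = b[flips])
  structure(list(
    n_pairs = length(a),
    mean_abs_diff = mean(d, na.rm = TRUE),
    max_abs_diff = max(d, na.rm = TRUE),
    prop_exceeding = setNames(
      vapply(thresholds, function(th) mean(d > th, na.rm = TRUE), numeric(1)),
      paste0("gt_", format(thresholds))),
    n_sign_flips = sum(flips, na.rm = TRUE),
    sign_flips = flip_df,
    share_m2_larger = mean(abs(b) > abs(a), na.rm = TRUE)
  ), class = "qc_corcmp")
}

#' @export
print.qc_corcmp <- function(x, ...) {
  cat(sprintf(
    "Correlation comparison over %d pairs: mean |diff| = %.3f, max = %.3f\n",
    x$n_pairs, x$mean_abs_diff, x$max_abs_diff))
  cat("  share exceeding:",
      paste(sprintf("%s: %.0f%%", names(x$prop_exceeding),
                    100 * x$prop_exceeding), collapse = ", "), "\n")
  cat(sprintf("  sign flips: %d; |r2| > |r1| in %.0f%% of pairs\n",
              x$n_sign_flips, 100 * x$share_m2_larger))
  invisible(x)
}

#' Read a benchmark configuration from YAML
#'
#' @param path YAML file: variable -> national estimate (proportions in
#'   `[0, 1]` or means), plus an optional `source` label.
#' @return Named list with `estimates` (named numeric) and `source`.
#' @export
read_benchmark <- function(path) {
  raw <- yaml::read_yaml(path)
  src <- raw$source %||% "unspecified"
  raw$source <- NULL
  list(estimates = unlist(raw), source = src)
}

#' Stage-by-stage comparison of sample estimates against benchmarks
#'
#' Assembles, per variable, the unweighted estimate, the estimate after
#' excluding fake-condition endorsers, the weighted estimate, the benchmark
#' value, and the absolute deviation from the benchmark at each stage —
#' mirroring the all / no-fake / weighted column layout of a
#' benchmark-comparison table.
#'
#' @param est_all named estimates on the full sample.
#' @param est_nofake named estimates excluding fake endorsers.
#' @param est_weighted named estimates after weighting.
#' @param benchmark named benchmark values (or a [read_benchmark()] list).
#' @return A data.frame with one row per benchmark variable, columns
#'   `variable`, `all`, `no_fake`, `weighted`, `benchmark`, `dev_all`,
#'   `dev_no_fake`, `dev_weighted`.
#' @export
benchmark_table <- function(est_all, est_nofake, est_weighted, benchmark) {
  if (is.list(benchmark) && !is.null(benchmark$estimates)) {
    benchmark <- benchmark$estimates
  }
  vars <- names(benchmark)
  missing <- setdiff(vars, names(est_all))
  if (length(missing)) {
    stop("benchmark variable missing from estimates: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    variable = vars,
    all = as.numeric(est_all[vars]),
    no_fake = as.numeric(est_nofake[vars]),
    weighted = as.numeric(est_weighted[vars]),
    benchmark = as.numeric(benchmark))
  out$dev_all <- abs(out$all - out$benchmark)
  out$dev_no_fake <- abs(out$no_fake - out$benchmark)
  out$dev_weighted <- abs(out$weighted - out$benchmark)
  out
}
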