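#' Cronbach alpha for a multi-item scale
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`, computed
#' on listwise-complete respondents within the scale (pairwise covariances
#' available as an option). Reverse-worded items are recoded to
#' `min + max - response` on the declared range before computation.
#'
#' @param responses response matrix (optional `respondent_id` column).
#' @param items scale item IDs (or a codebook scale list with `items` and
#'   `reverse`).
#' @param reverse subset of `items` that are reverse-worded.
#' @param range declared response range, default 1-5.
#' @param use `"listwise"` (default) or `"pairwise"` case handling.
#' @return A list of class `qc_alpha`: `alpha`, `n` (cases used), `k` (items).
#'   `alpha` is `NA` when undefined (zero total-score variance or fewer than
#'   3 complete cases).
#' @export
cronbach_alpha <- function(responses, items, reverse = character(),
                           range = c(1L, 5L), use = "listwise") {
  if (is.list(items) && !is.null(items$items)) {
    reverse <- items$reverse %||% character()
    items <- items$items
  }
  stopifnot(length(items) >= 2L)
  m <- battery_matrix(responses, items)
  storage.mode(m) <- "double"
  for (it in reverse) m[, it] <- range[1] + range[2] - m[, it]

  use <- match.arg(use, c("listwise", "pairwise"))
  if (use == "listwise") {
    m <- m[stats::complete.cases(m), , drop = FALSE]
    n <- nrow(m)
    if (n < 3L) {
      return(structure(list(alpha = NA_real_, n = n, k = length(items)),
                       class = "qc_alpha"))
    }
    v <- stats::var(m)
  } else {
    n <- min(crossprod(!is.na(m)))
    v <- stats::var(m, use = "pairwise.complete.obs")
  }
  total_var <- sum(v)
  k <- length(items)
  alpha <- if (is.na(total_var) || total_var <= 0) {
    NA_real_
  } else {
    k / (k - 1) * (1 - sum(diag(v)) / total_var)
  }
  structure(list(alpha = alpha, n = as.integer(n), k = k),
            class = "qc_alpha")
}

#' @export
print.qc_alpha <- function(x, ...) {
  cat(sprintf("Cronbach alpha = %.3f (k = %d items, n = %d cases)\n",
              x$alpha, x$k, x$n))
  invisible(x)
}

#' Test equality of two Cronbach alphas from independent samples
#'
#' Feldt-type test on `W = (1 - alpha1) / (1 - alpha2)`. Under the parallel
#' model and the null of equal reliabilities, each `(1 - alpha_hat)` term is
#' proportional to an F variate with `(n - 1, (n - 1)(k - 1))` degrees of
#' freedom, so `log(W)` is a difference of two log-F variates. The primary
#' p-value (two-sided) comes from a normal approximation to `log(W)` using
#' the exact digamma/trigamma moments of those log-F components — this keeps
#' the test calibrated for scales with few items, where the error degrees of
#' freedom `(n - 1)(k - 1)` are not ignorable. Also returned are the
#' classical `F(n1 - 1, n2 - 1)` p-value and a chi-square form (`z^2` on 1 df)
#' so either reporting convention can be matched.
#'
#' @param alpha1,alpha2 sample alphas (both `< 1`).
#' @param n1,n2 sample sizes (cases used).
#' @param k1,k2 numbers of items in each scale.
#' @return A list of class `qc_alpha_test`: `W`, `statistic` (z), `p_value`
#'   (primary), `chisq`, `df_chisq`, `p_chisq`, `p_f` (plain F convention),
#'   `df_f`.
#' @export
compare_alphas <- function(alpha1, n1, k1, alpha2, n2, k2) {
  if (alpha1 >= 1 || alpha2 >= 1) {
    stop("alpha must be < 1 for the reliability comparison", call. = FALSE)
  }
  stopifnot(n1 > k1, n2 > k2, k1 >= 2, k2 >= 2)
  W <- (1 - alpha1) / (1 - alpha2)

  # log-F moments: ln F(a, b) has mean psi(a/2)-ln(a/2)-psi(b/2)+ln(b/2)
  # and variance psi'(a/2)+psi'(b/2)
  lf_mean <- function(a, b) {
    digamma(a / 2) - log(a / 2) - digamma(b / 2) + log(b / 2)
  }
  lf_var <- function(a, b) trigamma(a / 2) + trigamma(b / 2)
  a1 <- n1 - 1; b1 <- (n1 - 1) * (k1 - 1)
  a2 <- n2 - 1; b2 <- (n2 - 1) * (k2 - 1)
  mu <- lf_mean(a1, b1) - lf_mean(a2, b2)
  sigma <- sqrt(lf_var(a1, b1) + lf_var(a2, b2))
  z <- (log(W) - mu) / sigma
  p <- 2 * stats::pnorm(-abs(z))

  p_f <- 2 * min(stats::pf(W, n1 - 1, n2 - 1),
                 stats::pf(W, n1 - 1, n2 - 1, lower.tail = FALSE))
  p_f <- min(p_f, 1)

  structure(list(W = W, statistic = z, p_value = p,
                 chisq = z^2, df_chisq = 1L, p_chisq = p,
                 p_f = p_f, df_f = c(n1 - 1, n2 - 1)),
            class = "qc_alpha_test")
}

#' @export
print.qc_alpha_test <- function(x, ...) {
  cat(sprintf(
    "Reliability comparison: W = %.3f, z = %.2f, p = %.3g (chi-square %.2f on 1 df)\n",
    x$W, x$statistic, x$p_value, x$chisq))
  invisible(x)
}

#' Alphas for every scale of a codebook, with optional cross-sample tests
#'
#' @param responses response matrix for one sample.
#' @param codebook a `qc_codebook`.
#' @param use case handling passed to [cronbach_alpha()].
#' @return Named list of `qc_alpha` per scale.
#' @export
scale_alphas <- function(responses, codebook = default_codebook(),
                         use = "listwise") {
  lapply(codebook$scales, function(sc) {
    cronbach_alpha(responses, sc, range = codebook$range, use = use)
  })
}
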