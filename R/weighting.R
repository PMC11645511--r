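#' Total absolute imbalance between weighted margins and targets
#'
#' Sum over raking variables and categories of the absolute difference
#' between the weighted sample proportion and the target proportion, on the
#' proportion scale. With `per_variable = TRUE` each variable's sum is
#' divided by the number of variables instead.
#'
#' @param demographics data.frame of raking variables (factors or character).
#' @param weights per-respondent weights.
#' @param targets named list: variable -> named target proportions.
#' @param per_variable normalize by the number of variables, default FALSE.
#' @return Non-negative scalar; 0 iff every margin matches its target.
#' @export
total_absolute_imbalance <- function(demographics, weights, targets,
                                     per_variable = FALSE) {
  tot <- 0
  for (v in names(targets)) {
    tv <- targets[[v]]
    obs <- weighted_margin(demographics[[v]], weights, names(tv))
    tot <- tot + sum(abs(obs - tv))
  }
  if (per_variable) tot / length(targets) else tot
}

weighted_margin <- function(x, w, categories) {
  x <- as.character(x)
  unknown <- setdiff(unique(x), categories)
  if (length(unknown)) {
    stop("categories absent from targets: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  s <- vapply(categories, function(cc) sum(w[x == cc]), numeric(1))
  s / sum(w)
}

#' Read marginal raking targets from YAML
#'
#' @param path YAML file: variable -> category -> proportion.
#' @param tol tolerance on each variable's sum, default 1e-6; proportions are
#'   renormalized to sum exactly to 1 within it.
#' @return Named list of named proportion vectors.
#' @export
read_targets <- function(path, tol = 1e-6) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(v) unlist(v))
  for (nm in names(out)) {
    s <- sum(out[[nm]])
    if (abs(s - 1) > tol) {
      stop("targets for ", nm, " sum to ", format(s), ", not 1", call. = FALSE)
    }
    out[[nm]] <- out[[nm]] / s
  }
  out
}

#' Raking (iterative proportional fitting) with trimming and scaling
#'
#' Starting from base weights (default 1), cycles through the raking
#' variables in the order given, multiplying each respondent's weight by
#' `target / current weighted proportion` for their category. After each full
#' cycle, weights above `max_weight` are trimmed to it and all weights are
#' rescaled to mean 1 (so the cap is enforced inside the iteration, not as a
#' single post-hoc step). Iteration stops once the total absolute imbalance
#' falls to `tol` or `max_iter` cycles have run.
#'
#' Respondents with a missing value on a raking variable are placed in an
#' explicit `"(missing)"` category raked to its own unweighted sample share
#' (weight-neutral), with the variable's stated targets rescaled to the
#' complement.
#'
#' @param demographics data.frame of raking variables.
#' @param targets named list: variable -> named target proportions (each
#'   summing to 1).
#' @param base_weights starting weights, default 1.
#' @param max_weight trim cap on individual weights (on the mean-1 scale).
#' @param tol convergence tolerance on total absolute imbalance, default 1e-6.
#' @param max_iter maximum cycles, default 200.
#' @return A list of class `rake_weights`: `weights` (mean 1), `iterations`,
#'   `converged`, `max_weight` (cap), `n_trimmed` (weights at cap on exit),
#'   `total_absolute_imbalance`.
#' @export
rake <- function(demographics, targets, base_weights = NULL, max_weight = 30,
                 tol = 1e-6, max_iter = 200L) {
  n <- nrow(demographics)
  stopifnot(n > 0, max_weight > 1)
  for (v in names(targets)) {
    if (!v %in% names(demographics)) {
      stop("raking variable absent from demographics: ", v, call. = FALSE)
    }
    if (any(targets[[v]] < 0)) stop("negative target in ", v, call. = FALSE)
    assert_proportions(targets[[v]], paste0("targets$", v), tol = 1e-6)
  }

  # explicit missing category raked to its sample share
  dem <- demographics[names(targets)]
  targets_use <- targets
  for (v in names(targets)) {
    x <- as.character(dem[[v]])
    if (anyNA(x)) {
      share <- mean(is.na(x))
      x[is.na(x)] <- "(missing)"
      targets_use[[v]] <- c(targets[[v]] * (1 - share),
                            "(missing)" = share)
    }
    dem[[v]] <- x
    tv <- targets_use[[v]]
    empty <- setdiff(names(tv)[tv > 0], unique(x))
    if (length(empty)) {
      stop("no respondents in category with nonzero target: ", v, " = ",
           paste(empty, collapse = ", "), call. = FALSE)
    }
  }

  w <- base_weights %||% rep(1, n)
  stopifnot(length(w) == n, all(w > 0))
  w <- w / mean(w)

  converged <- FALSE
  iter <- 0L
  imb <- total_absolute_imbalance(dem, w, targets_use)
  while (iter < max_iter && imb > tol) {
    iter <- iter + 1L
    for (v in names(targets_use)) {
      tv <- targets_use[[v]]
      obs <- weighted_margin(dem[[v]], w, names(tv))
      fac <- ifelse(obs > 0, tv / obs, 1)
      w <- w * unname(fac[match(dem[[v]], names(tv))])
    }
    # trim-then-rescale to mean 1; repeat so rescaling cannot push any
    # weight back above the cap
    for (rep_i in 1:50) {
      w <- pmin(w / mean(w), max_weight)
      if (abs(mean(w) - 1) < 1e-12) break
    }
    w <- w / mean(w)
    w <- pmin(w, max_weight)
    imb <- total_absolute_imbalance(dem, w, targets_use)
  }
  converged <- imb <= tol

  structure(list(weights = w, iterations = iter, converged = converged,
                 max_weight = max_weight,
                 n_trimmed = sum(w >= max_weight - 1e-12),
                 total_absolute_imbalance = imb),
            class = "rake_weights")
}

#' @export
print.rake_weights <- function(x, ...) {
  cat(sprintf(paste0(
    "Raking weights: n = %d, %d cycles, %s (total absolute imbalance %.3g)\n",
    "  max weight %.2f (cap %.1f, %d at cap), mean 1\n"),
    length(x$weights), x$iterations,
    if (x$converged) "converged" else "not converged",
    x$total_absolute_imbalance, max(x$weights), x$max_weight, x$n_trimmed))
  invisible(x)
}

#' Weighted estimates with effective sample size
#'
#' Hajek-style weighted mean for numeric input, weighted category proportions
#' for factor/character input; the effective sample size is
#' `(sum w)^2 / sum(w^2)` (equal to n iff all weights are equal).
#'
#' @param values numeric, factor, or character vector.
#' @param weights per-respondent weights (e.g. from [rake()]).
#' @return A list: `estimate` (scalar mean or named proportions), `ess`, `n`.
#' @export
weighted_estimates <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  ok <- !is.na(values) & !is.na(weights)
  if (!any(ok)) stop("no non-missing values", call. = FALSE)
  v <- values[ok]; w <- weights[ok]
  est <- if (is.numeric(v)) {
    sum(w * v) / sum(w)
  } else {
    lv <- if (is.factor(v)) levels(v) else sort(unique(as.character(v)))
    weighted_margin(as.character(v), w, lv)
  }
  list(estimate = est, ess = sum(w)^2 / sum(w^2), n = length(v))
}
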