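#' Weighted kappa for ordinal agreement
#'
#' Chance-corrected agreement between two ordinal ratings with disagreement
#' weights over the full declared category range:
#' `kappa = 1 - sum(w * O) / sum(w * E)`, where `O` is the observed joint
#' proportion table, `E` the chance table (outer product of the marginals),
#' and `w[i, j] = (i - j)^2` for the default quadratic scheme (`abs(i - j)`
#' for linear). Weights are built on the declared range even if some
#' categories are unobserved: the penalty depends on the metric of the scale,
#' not on the sample. Pairwise-complete observations are used.
#'
#' @param x,y equal-length ordinal vectors (integer categories).
#' @param range declared category range, default 1-5.
#' @param scheme `"quadratic"` (default) or `"linear"` disagreement weights.
#' @return Kappa in `[-1, 1]`, or `NA` if undefined (fewer than 2
#'   pairwise-complete cases, or a constant joint distribution leaving the
#'   expected disagreement zero).
#' @export
weighted_kappa <- function(x, y, range = c(1L, 5L), scheme = "quadratic") {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  cats <- seq(range[1], range[2])
  O <- table(factor(x, levels = cats), factor(y, levels = cats)) / length(x)
  px <- rowSums(O); py <- colSums(O)
  E <- outer(px, py)
  d <- abs(outer(cats, cats, "-"))
  w <- switch(match.arg(scheme, c("quadratic", "linear")),
              quadratic = d^2, linear = d)
  ed <- sum(w * E)
  if (ed == 0) return(NA_real_)  # degenerate marginals: chance agreement undefined
  1 - sum(w * O) / ed
}

#' Interpret a kappa value on the Landis-Koch scale
#'
#' Bands: below 0 poor; 0.00-0.20 slight; 0.21-0.40 fair; 0.41-0.60 moderate;
#' 0.61-0.80 substantial; 0.81-1.00 almost perfect. Kappa is rounded to two
#' decimals before banding, matching the precision at which kappas are
#' conventionally reported (so 0.205 rounds to 0.21, "fair").
#'
#' @param kappa numeric in `[-1, 1]`.
#' @return Character label (vectorised).
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(all(kappa >= -1 & kappa <= 1, na.rm = TRUE))
  # half-up rounding to 2 decimals (so 0.205 -> 0.21, "fair"), with an
  # epsilon guard against binary representation of values like 0.205
  k <- floor(kappa * 100 + 0.5 + 1e-9) / 100
  labels <- c("poor", "slight", "fair", "moderate", "substantial",
              "almost perfect")
  # cut between the 2-decimal bands (0.20|0.21 etc.); k < 0 is poor
  out <- labels[findInterval(k, c(0, 0.205, 0.405, 0.605, 0.805)) + 1L]
  out[is.na(kappa)] <- NA_character_
  out
}

battery_matrix <- function(responses, items) {
  m <- drop_id(responses)
  missing <- setdiff(items, colnames(m))
  if (length(missing)) {
    stop("battery items absent from responses: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m[, items, drop = FALSE]
}

# constant within battery, requiring the battery to be fully observed
battery_constant <- function(m) {
  complete <- rowSums(is.na(m)) == 0L
  const <- complete &
    apply(m, 1L, function(r) length(unique(r[!is.na(r)])) == 1L)
  list(complete = complete, const = const,
       value = ifelse(const, m[, 1L], NA_integer_))
}

#' Straight-lining rule 1: same category within every battery
#'
#' Flags respondents whose answered responses are identical within every
#' declared consecutive same-response-category set. Batteries with any
#' missing item are treated conservatively: such a respondent is not flagged.
#'
#' @param responses response matrix (with optional `respondent_id` column).
#' @param batteries codebook battery list (each with an `items` element).
#' @return Logical flags.
#' @export
straightline_all_sets <- function(responses, batteries) {
  stopifnot(length(batteries) >= 1L)
  flags <- rep(TRUE, nrow(drop_id(responses)))
  for (b in batteries) {
    bc <- battery_constant(battery_matrix(responses, b$items))
    flags <- flags & bc$const
  }
  flags
}

#' Straight-lining rule for a single battery with an allowed category
#'
#' Flags respondents who give one identical response to all items of the
#' battery, unless that common response equals the battery's allowed
#' category (e.g. "without any difficulty" on a physical-function set, or the
#' middle category on mixed-direction sleep sets). Respondents with any
#' missing item in the battery are not flagged.
#'
#' @param responses response matrix.
#' @param battery a codebook battery (`items`, `allowed`).
#' @return Logical flags.
#' @export
straightline_battery <- function(responses, battery) {
  bc <- battery_constant(battery_matrix(responses, battery$items))
  if (is.null(battery$allowed) || is.na(battery$allowed)) return(bc$const)
  bc$const & bc$value != battery$allowed
}

#' Mean root of pairs: a battery-level straight-lining score
#'
#' For each respondent, the mean over all item pairs in the battery of the
#' square root of the absolute response difference, rescaled by the square
#' root of the declared range span and reflected so that 1 is maximal
#' straight-lining (all responses identical) and 0 is maximal spread:
#' `rp = 1 - mean(sqrt(|r_i - r_j|)) / sqrt(max - min)`.
#'
#' @param responses response matrix.
#' @param items battery item IDs.
#' @param range declared category range, default 1-5.
#' @return Numeric vector of per-respondent scores in `[0, 1]`; `NA` for
#'   respondents with fewer than 2 answered items in the battery.
#' @export
mean_root_of_pairs <- function(responses, items, range = c(1L, 5L)) {
  m <- battery_matrix(responses, items)
  span <- sqrt(range[2] - range[1])
  apply(m, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) return(NA_real_)
    pairs <- utils::combn(length(r), 2L)
    1 - mean(sqrt(abs(r[pairs[1L, ]] - r[pairs[2L, ]]))) / span
  })
}

#' Winsorized response-burden summary
#'
#' Durations above the 97.5th percentile are capped to that percentile value
#' (linear-interpolation percentile, the standard definition), then the mean,
#' SD, median, minimum and maximum are computed on the capped values.
#'
#' Capping at a given cap value is a projection (applying it twice changes
#' nothing), but re-estimating the percentile from already-capped data can
#' lower it again under the interpolated percentile definition; pass `cap` to
#' summarise new data under a previously estimated cap.
#'
#' @param durations durations in seconds.
#' @param cap_quantile upper quantile to cap at, default 0.975.
#' @param units `"minutes"` (default) or `"seconds"` for the output scale.
#' @param cap optional pre-computed cap in seconds; when `NULL` (default) the
#'   `cap_quantile` percentile of `durations` is used.
#' @return Named list: `mean`, `sd`, `median`, `min`, `max`, `cap`.
#' @export
winsorized_burden <- function(durations, cap_quantile = 0.975,
                              units = "minutes", cap = NULL) {
  stopifnot(length(durations) >= 1L)
  x <- durations[!is.na(durations)]
  cap <- cap %||% stats::quantile(x, cap_quantile, names = FALSE, type = 7)
  x <- pmin(x, cap)
  scale <- switch(match.arg(units, c("minutes", "seconds")),
                  minutes = 60, seconds = 1)
  list(mean = mean(x) / scale, sd = stats::sd(x) / scale,
       median = stats::median(x) / scale,
       min = min(x) / scale, max = max(x) / scale, cap = cap / scale)
}

#' Compute the full careless-response metric bundle for one sample
#'
#' Evaluates, against a codebook: weighted kappa (with interpretation) for
#' every declared consistency pair, the three straight-lining rules (all
#' sets; the 6-item physical-function battery with ratings of 5 allowed; one
#' or both 3-item sleep sets with ratings of 3 allowed), mean root of pairs
#' for both sleep sets, the share of respondents who answered every item, and
#' the Winsorized response burden.
#'
#' @param responses analytic response matrix (with `respondent_id`).
#' @param durations durations data.frame aligned to `responses` (rows for the
#'   same respondents), or `NULL` to skip the burden summary.
#' @param codebook a `qc_codebook`.
#' @return A list of class `qc_careless` with elements `kappa`,
#'   `straightlining`, `root_of_pairs`, `complete_all_items`, `burden`, `n`.
#' @export
careless_metrics <- function(responses, durations = NULL,
                             codebook = default_codebook()) {
  rng <- codebook$range
  kap <- lapply(codebook$pairs, function(p) {
    k <- weighted_kappa(responses[[p[1]]], responses[[p[2]]], range = rng)
    list(items = p, kappa = k, interpretation = interpret_kappa(k))
  })

  all_sets <- straightline_all_sets(responses, codebook$batteries)
  pf <- straightline_battery(responses, codebook$batteries$physical_function6)
  sleep <- straightline_battery(responses, codebook$batteries$sleep_set1) |
    straightline_battery(responses, codebook$batteries$sleep_set2)
  n <- nrow(responses)
  sl <- list(
    all_sets = list(n = sum(all_sets), pct = 100 * mean(all_sets)),
    physical_function6 = list(n = sum(pf), pct = 100 * mean(pf)),
    sleep_sets = list(n = sum(sleep), pct = 100 * mean(sleep))
  )

  rp1 <- mean_root_of_pairs(responses, codebook$batteries$sleep_set1$items, rng)
  rp2 <- mean_root_of_pairs(responses, codebook$batteries$sleep_set2$items, rng)
  rp <- list(
    sleep_set1 = list(mean = mean(rp1, na.rm = TRUE),
                      sd = stats::sd(rp1, na.rm = TRUE)),
    sleep_set2 = list(mean = mean(rp2, na.rm = TRUE),
                      sd = stats::sd(rp2, na.rm = TRUE))
  )

  m <- drop_id(responses)
  complete_all <- rowSums(is.na(m)) == 0L

  structure(list(
    kappa = kap,
    straightlining = sl,
    root_of_pairs = rp,
    complete_all_items = list(n = sum(complete_all),
                              pct = 100 * mean(complete_all)),
    burden = if (!is.null(durations)) winsorized_burden(durations$duration_s),
    n = n
  ), class = "qc_careless")
}
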