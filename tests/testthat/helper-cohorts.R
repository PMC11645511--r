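# Shared fixtures, generated in code and memoised across test files.

.fixture_env <- new.env(parent = emptyenv())

memo_cohort <- function(key, maker) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- maker()
  .fixture_env[[key]]
}

# mid-size default-condition cohort reused by several files
std_cohort <- function() {
  memo_cohort("std", function() {
    generate_cohort(persona_config(n = 3000, seed = 402))
  })
}

# screened version of the same cohort
std_screened <- function() {
  memo_cohort("std_screen", function() {
    co <- std_cohort()
    build_analytic(co$responses, co$durations, co$endorsements,
                   n_fielded = 6000)
  })
}

# full-scale two-panel pipeline, run once and shared
full_pipeline_report <- function() {
  memo_cohort("full_pipe", function() {
    run_pipeline(pipeline_config(seed = 314))
  })
}

# independent direct-summation oracle for weighted kappa: explicit loops,
# no shared code with the implementation
kappa_oracle <- function(x, y, range = c(1L, 5L), power = 2) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  cats <- seq(range[1], range[2])
  n <- length(x)
  obs_dis <- 0
  for (i in seq_len(n)) obs_dis <- obs_dis + abs(x[i] - y[i])^power
  obs_dis <- obs_dis / n
  exp_dis <- 0
  for (a in cats) {
    for (b in cats) {
      exp_dis <- exp_dis + mean(x == a) * mean(y == b) * abs(a - b)^power
    }
  }
  1 - obs_dis / exp_dis
}

# sort-based percentile with linear interpolation, written independently of
# stats::quantile, for the Winsorization oracle
percentile_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force alpha from the covariance definition, independent path
alpha_oracle <- function(m) {
  k <- ncol(m)
  item_vars <- numeric(k)
  for (j in seq_len(k)) item_vars[j] <- stats::var(m[, j])
  total <- stats::var(rowSums(m))
  k / (k - 1) * (1 - sum(item_vars) / total)
}

# random joint contingency table -> paired ordinal vectors
random_pair_from_table <- function(n_cat = 5L, n = 60L) {
  counts <- as.vector(stats::rmultinom(1, n, rep(1, n_cat^2)))
  tab <- matrix(counts, n_cat)
  x <- rep(rep(seq_len(n_cat), n_cat), counts)
  y <- rep(rep(seq_len(n_cat), each = n_cat), counts)
  list(x = x, y = y, tab = tab)
}
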