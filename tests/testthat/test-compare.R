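test_that("T-score standardization anchors at mean 50, SD 10", {
  set.seed(2)
  ref <- rnorm(500, 3, 1.2)
  t_ref <- tscore_standardize(ref, ref)
  expect_equal(mean(t_ref), 50)
  expect_equal(sd(t_ref), 10)
  expect_equal(tscore_standardize(mean(ref) + sd(ref), ref), 60)

  # affine invariance: transforming scores and reference together
  expect_equal(tscore_standardize(2 + 3 * ref, 2 + 3 * ref), t_ref)
  expect_error(tscore_standardize(1:5, rep(4, 10)), "distinct")
})

test_that("the small-effect flag is strict and symmetric", {
  expect_false(effect_flag(52, 50))
  expect_true(effect_flag(52.1, 50))
  expect_identical(effect_flag(47, 50), effect_flag(50, 47))
})

test_that("correlation matrix cells and intervals are well formed", {
  set.seed(10)
  n <- 10000
  x <- rnorm(n); y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  cm <- correlation_matrix(data.frame(x = x, y = y, neg = -x))
  expect_equal(diag(cm$r), c(x = 1, y = 1, neg = 1))
  expect_equal(cm$r["x", "neg"], -1)
  expect_true(cm$lower["x", "y"] <= 0.5 && 0.5 <= cm$upper["x", "y"])
  expect_true(all(cm$lower <= cm$r + 1e-12 & cm$r <= cm$upper + 1e-12,
                  na.rm = TRUE))

  cm2 <- correlation_matrix(data.frame(a = 1:5, b = rep(2, 5)))
  expect_true(is.na(cm2$r["a", "b"]))
})

test_that("matrix comparison equals direct enumeration on a hand case", {
  r1 <- matrix(c(1, .5, -.2, .5, 1, .3, -.2, .3, 1), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  r2 <- matrix(c(1, .62, .1, .62, 1, .24, .1, .24, 1), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  cmp <- compare_correlation_matrices(r1, r2)
  diffs <- c(abs(.5 - .62), abs(-.2 - .1), abs(.3 - .24))
  expect_equal(cmp$n_pairs, 3)
  expect_equal(cmp$mean_abs_diff, mean(diffs))
  expect_equal(cmp$max_abs_diff, max(diffs))
  expect_equal(unname(cmp$prop_exceeding),
               c(mean(diffs > .05), mean(diffs > .10), mean(diffs > .15),
                 mean(diffs > .20)))
  expect_equal(unname(cmp$prop_exceeding), c(1, 2 / 3, 1 / 3, 1 / 3))
  expect_equal(cmp$n_sign_flips, 1)
  expect_equal(cmp$share_m2_larger, 1 / 3)  # only .62 beats .5 in magnitude

  same <- compare_correlation_matrices(r1, r1)
  expect_equal(same$mean_abs_diff, 0)
  expect_equal(same$n_sign_flips, 0)

  flipped <- compare_correlation_matrices(r1, -r1)
  expect_equal(flipped$n_sign_flips, 3)
})

test_that("comparison commutes with relabeling variable order", {
  set.seed(3)
  m <- matrix(rnorm(300), 100)
  colnames(m) <- c("u", "v", "w")
  c1 <- correlation_matrix(m)
  c2 <- correlation_matrix(m[, c("w", "u", "v")])
  cmp <- compare_correlation_matrices(c1, c2)
  expect_equal(cmp$mean_abs_diff, 0)
  expect_equal(cmp$n_sign_flips, 0)
})

test_that("planted opposite education-health links appear as sign flips", {
  eff_pos <- list(physical_function = list(
    education = c(no_hs = -0.5, hs_grad = -0.25, some_college = 0,
                  bachelor = 0.25, masters_plus = 0.5)))
  eff_neg <- list(physical_function = list(
    education = c(no_hs = 0.5, hs_grad = 0.25, some_college = 0,
                  bachelor = -0.25, masters_plus = -0.5)))
  mk <- function(eff, seed) {
    generate_cohort(persona_config(
      n = 1500, seed = seed, incomplete_rate = 0, miss_rate = 0,
      persona_mix = c(attentive = 1, straightliner = 0, speeder = 0,
                      misrepresenter = 0, copier = 0),
      demo_bias = list(), trait_demo_effects = eff))
  }
  co_a <- mk(eff_pos, 61); co_b <- mk(eff_neg, 62)
  frame <- function(co) {
    cb <- co$config$codebook
    pf <- rowMeans(drop_id(co$responses)[, cb$scales$physical_function$items])
    edu <- as.numeric(co$demographics$education)
    data.frame(pf = pf, edu = edu)
  }
  cma <- correlation_matrix(frame(co_a))
  cmb <- correlation_matrix(frame(co_b))
  expect_gt(cma$r["pf", "edu"], 0.05)
  expect_lt(cmb$r["pf", "edu"], -0.05)
  expect_equal(compare_correlation_matrices(cma, cmb)$n_sign_flips, 1)
})

test_that("benchmark table tracks deviations across the three stages", {
  bench <- c(v1 = 0.5, v2 = 0.2)
  tab <- benchmark_table(c(v1 = 0.6, v2 = 0.2), c(v1 = 0.55, v2 = 0.21),
                         c(v1 = 0.5, v2 = 0.2), bench)
  expect_equal(names(tab), c("variable", "all", "no_fake", "weighted",
                             "benchmark", "dev_all", "dev_no_fake",
                             "dev_weighted"))
  expect_equal(tab$dev_weighted, c(0, 0))
  expect_equal(tab$dev_all, c(0.1, 0))
  expect_error(benchmark_table(c(v1 = .1), c(v1 = .1), c(v1 = .1),
                               c(v9 = .5)), "missing")
})

test_that("weighting moves raking-variable margins toward the benchmark", {
  co <- std_cohort()
  targets <- co$config$demo_marginals
  dem <- co$demographics[names(targets)]
  # uncapped so the margins converge fully: the per-category guarantee is a
  # property of the converged fit, not of a trimmed one
  rw <- rake(dem, targets, max_weight = Inf)
  flat_t <- unlist(lapply(names(targets), function(v) {
    setNames(targets[[v]], paste(v, names(targets[[v]]), sep = "."))
  }))
  unw <- flatten_margins(dem)
  wtd <- flatten_margins(dem, rw$weights)
  tab <- benchmark_table(unw, unw, wtd, flat_t)
  expect_true(all(tab$dev_weighted <= tab$dev_all + 1e-9))
})
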