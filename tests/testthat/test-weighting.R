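test_that("imbalance is a sum of absolute margin deviations", {
  dem <- data.frame(g = c("a", "a", "b", "b"))
  w <- rep(1, 4)
  expect_equal(total_absolute_imbalance(dem, w, list(g = c(a = .5, b = .5))), 0)
  expect_equal(total_absolute_imbalance(dem, w, list(g = c(a = .52, b = .48))),
               0.04)
  expect_gte(total_absolute_imbalance(dem, w, list(g = c(a = .9, b = .1))), 0)
  expect_error(total_absolute_imbalance(
    data.frame(g = c("a", "zz")), c(1, 1), list(g = c(a = 1, b = 0))),
    "absent from targets")
})

test_that("raking leaves an already-balanced sample untouched", {
  dem <- data.frame(g = rep(c("a", "b"), each = 50))
  rw <- rake(dem, list(g = c(a = .5, b = .5)))
  expect_true(rw$converged)
  expect_lte(rw$iterations, 1)
  expect_equal(rw$weights, rep(1, 100))
})

test_that("one-variable raking matches the closed form exactly", {
  dem <- data.frame(g = rep(c("a", "b"), times = c(60, 40)))
  rw <- rake(dem, list(g = c(a = .5, b = .5)))
  expected <- ifelse(dem$g == "a", .5 / .6, .5 / .4)
  expected <- expected / mean(expected)
  expect_equal(rw$weights, expected, tolerance = 1e-9)
  expect_equal(mean(rw$weights), 1)
})

test_that("converged margins match targets when trimming never activates", {
  co <- std_cohort()
  targets <- co$config$demo_marginals
  rw <- rake(co$demographics[names(targets)], targets, max_weight = Inf)
  expect_true(rw$converged)
  expect_lte(rw$total_absolute_imbalance, 1e-6)
  expect_equal(rw$n_trimmed, 0)
  expect_equal(mean(rw$weights), 1, tolerance = 1e-9)
  for (v in names(targets)) {
    obs <- weighted_margin(as.character(co$demographics[[v]]), rw$weights,
                           names(targets[[v]]))
    expect_lt(max(abs(obs - targets[[v]])), 1e-6 / length(targets))
  }
})

test_that("a binding cap is still honoured on a multi-variable cohort", {
  co <- std_cohort()
  targets <- co$config$demo_marginals
  rw <- rake(co$demographics[names(targets)], targets, max_weight = 30)
  expect_lte(max(rw$weights), 30 + 1e-9)
  expect_equal(mean(rw$weights), 1, tolerance = 1e-9)
})

test_that("a tight cap binds and is never exceeded", {
  set.seed(9)
  dem <- data.frame(g = sample(c("a", "b"), 400, TRUE, prob = c(.95, .05)))
  rw <- rake(dem, list(g = c(a = .5, b = .5)), max_weight = 3, max_iter = 50)
  expect_lte(max(rw$weights), 3 + 1e-9)
  expect_gt(rw$n_trimmed, 0)
  expect_false(rw$converged)  # the cap prevents matching these targets
})

test_that("variable order does not change the converged weights", {
  co <- std_cohort()
  targets <- co$config$demo_marginals
  dem <- co$demographics[names(targets)]
  # without trimming the IPF fixed point is unique, so the cycling order
  # cannot matter at convergence
  rw1 <- rake(dem, targets, max_weight = Inf)
  rw2 <- rake(dem, rev(targets), max_weight = Inf)
  expect_equal(rw1$weights, rw2$weights, tolerance = 1e-4)
})

test_that("raking recovers a population trait mean under selection bias", {
  cfg <- persona_config(n = 6000, seed = 204, persona_mix = c(
    attentive = 1, straightliner = 0, speeder = 0, misrepresenter = 0,
    copier = 0), incomplete_rate = 0)
  co <- generate_cohort(cfg)
  targets <- cfg$demo_marginals
  rw <- rake(co$demographics[names(targets)], targets, max_weight = 100)
  expect_true(rw$converged)

  # estimand from the generator's own marginals: age shifts physical function
  eff <- cfg$trait_demo_effects$physical_function$age
  pop_mean <- sum(cfg$demo_marginals$age * eff[names(cfg$demo_marginals$age)])
  tr <- co$truth$trait_physical_function
  est <- weighted_estimates(tr, rw$weights)
  w <- rw$weights / sum(rw$weights)
  mc_se <- sqrt(sum(w^2) * stats::var(tr))
  expect_lt(abs(est$estimate - pop_mean), 3 * mc_se)

  # the unweighted mean is visibly biased by comparison
  expect_gt(abs(mean(tr) - pop_mean), abs(est$estimate - pop_mean))
})

test_that("missing demographics go to a weight-neutral explicit category", {
  dem <- data.frame(g = c(rep("a", 45), rep("b", 45), rep(NA, 10)))
  rw <- rake(dem, list(g = c(a = .5, b = .5)))
  expect_true(rw$converged)
  # the missing tenth keeps its sample share of the weight
  expect_equal(sum(rw$weights[is.na(dem$g)]) / sum(rw$weights), 0.1,
               tolerance = 1e-6)
})

test_that("impossible targets raise errors", {
  dem <- data.frame(g = rep("a", 10))
  expect_error(rake(dem, list(g = c(a = .5, b = .5))), "no respondents")
  expect_error(rake(dem, list(g = c(a = 1.5, b = -0.5))), "negative")
  expect_error(rake(dem, list(h = c(a = 1))), "absent")
})

test_that("weighted estimates and effective sample size behave", {
  expect_equal(weighted_estimates(c(10, 4), c(2, 1))$estimate, 8)
  expect_equal(weighted_estimates(1:10, rep(2, 10))$estimate, mean(1:10))
  set.seed(1)
  w <- rexp(50) + .1
  e <- weighted_estimates(rnorm(50), w)
  expect_lte(e$ess, 50)
  expect_equal(weighted_estimates(rnorm(50), rep(3, 50))$ess, 50)
  p <- weighted_estimates(factor(c("x", "x", "y")), c(1, 1, 2))$estimate
  expect_equal(unname(p), c(0.5, 0.5))
  expect_error(weighted_estimates(c(NA, NA), c(1, 1)), "non-missing")
})
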