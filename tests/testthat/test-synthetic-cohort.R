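test_that("configuration invariants are enforced", {
  expect_error(persona_config(persona_mix = c(attentive = 0.8, straightliner = 0.1,
                                              speeder = 0, misrepresenter = 0.05,
                                              copier = 0.1)),
               "sum to 1")
  bad_corr <- default_trait_corr()
  bad_corr[1, 2] <- bad_corr[2, 1] <- 2  # breaks positive semi-definiteness
  expect_error(persona_config(trait_corr = bad_corr), "positive semi-definite")
  expect_error(persona_config(demo_bias = list(age = c(nonexistent = 2))),
               "unknown category")
})

test_that("an all-attentive cohort has no planted artifacts", {
  cfg <- persona_config(
    n = 500,
    persona_mix = c(attentive = 1, straightliner = 0, speeder = 0,
                    misrepresenter = 0, copier = 0),
    incomplete_rate = 0, seed = 11)
  co <- generate_cohort(cfg)
  expect_true(all(co$truth$persona == "attentive"))
  expect_equal(sum(co$endorsements$syndomitis), 0)
  expect_equal(sum(co$endorsements$chekalism), 0)
  expect_true(all(co$durations$duration_s / co$durations$items_assigned >= 1))
  expect_equal(sum(find_copied(co$texts)$flags), 0)
})

test_that("the same seed reproduces the cohort exactly", {
  cfg <- persona_config(n = 300, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("persona mixture is recovered within binomial error at large n", {
  co <- memo_cohort("big_mix", function() {
    generate_cohort(persona_config(n = 6000, seed = 21))
  })
  mix <- co$config$persona_mix
  realized <- table(factor(co$truth$persona, levels = names(mix))) / co$config$n
  for (p in names(mix)) {
    se <- sqrt(mix[p] * (1 - mix[p]) / co$config$n)
    expect_lt(abs(realized[p] - mix[p]), 3 * se + 1e-12)
  }
})

test_that("fake-endorsement rate matches its binomial expectation", {
  co <- memo_cohort("big_mix", function() {
    generate_cohort(persona_config(n = 6000, seed = 21))
  })
  cfg <- co$config
  flagged <- flag_fake_endorsers(co$endorsements)
  p_flag <- cfg$persona_mix[["misrepresenter"]] *
    (1 - (1 - cfg$fake_endorse_prob)^2)
  se <- sqrt(p_flag * (1 - p_flag) / cfg$n)
  expect_lt(abs(mean(flagged) - p_flag), 3 * se)
})

test_that("planted personas trip their designated detectors", {
  co <- std_cohort()
  truth <- co$truth
  cb <- co$config$codebook

  sl <- truth$persona == "straightliner" & !truth$incomplete
  r1 <- straightline_all_sets(co$responses, cb$batteries)
  r2 <- straightline_battery(co$responses, cb$batteries$physical_function6)
  r3 <- straightline_battery(co$responses, cb$batteries$sleep_set1) |
    straightline_battery(co$responses, cb$batteries$sleep_set2)
  expect_true(all((r1 | r2 | r3)[sl]))

  sp <- truth$persona == "speeder"
  if (any(sp)) {
    expect_true(all(filter_speeders(co$durations$duration_s,
                                    co$durations$items_assigned)[sp]))
  }

  cp <- truth$persona == "copier"
  td <- find_copied(co$texts)
  expect_true(all(td$flags[cp]))
})

test_that("speeder durations sit strictly below one second per item", {
  cfg <- persona_config(
    n = 400,
    persona_mix = c(attentive = 0.5, straightliner = 0, speeder = 0.5,
                    misrepresenter = 0, copier = 0),
    incomplete_rate = 0, seed = 5)
  co <- generate_cohort(cfg)
  sp <- co$truth$persona == "speeder"
  rate <- co$durations$duration_s / co$durations$items_assigned
  expect_true(all(rate[sp] < 1))
  expect_true(all(rate[!sp] >= 1))
})

test_that("demographic sampling follows bias-distorted marginals", {
  marg <- list(grp = c(a = 0.5, b = 0.3, c = 0.2))
  n <- 40000

  unbiased <- generate_demographics(marg, list(grp = c(a = 1, b = 1, c = 1)),
                                    n, seed = 3)
  for (cat in names(marg$grp)) {
    p <- marg$grp[cat]
    expect_lt(abs(mean(unbiased$grp == cat) - p), 3 * sqrt(p * (1 - p) / n))
  }

  # doubling one category's selection: realized share is 2p / (1 + p)
  doubled <- generate_demographics(marg, list(grp = c(b = 2)), n, seed = 4)
  p <- marg$grp[["b"]]
  expected <- 2 * p / (1 + p)
  expect_lt(abs(mean(doubled$grp == "b") - expected),
            3 * sqrt(expected * (1 - expected) / n))

  expect_equal(nrow(generate_demographics(marg, list(), 0, seed = 1)), 0)
  expect_error(generate_demographics(marg, list(grp = c(zz = 2)), 10),
               "unknown category")
})

test_that("incompleteness overlay answers less than half of the items", {
  cfg <- persona_config(n = 800, incomplete_rate = 0.2, seed = 31)
  co <- generate_cohort(cfg)
  inc <- co$truth$incomplete
  expect_gt(sum(inc), 0)
  answered <- rowSums(!is.na(drop_id(co$responses)))
  n_items <- ncol(drop_id(co$responses))
  expect_true(all(answered[inc] < n_items / 2))
})

test_that("cohort tables round-trip through CSV", {
  co <- generate_cohort(persona_config(n = 50, seed = 8))
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  expect_true(all(file.exists(files)))
  back <- utils::read.csv(files["responses"], check.names = FALSE)
  expect_equal(nrow(back), 50)
  expect_identical(names(back), names(co$responses))
  expect_equal(sum(is.na(back[, -1])), sum(is.na(co$responses[, -1])))
})
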