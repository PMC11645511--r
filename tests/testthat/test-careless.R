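test_that("weighted kappa matches hand-computed and oracle values", {
  # perfect agreement
  x <- c(1L, 2L, 3L, 4L, 5L, 2L, 4L)
  expect_equal(weighted_kappa(x, x), 1)

  # 3x3 joint table [[2,1,0],[1,2,1],[0,1,2]]: direct summation gives 2/3
  xx <- c(1, 1, 1, 2, 2, 2, 2, 3, 3, 3)
  yy <- c(1, 1, 2, 1, 2, 2, 3, 2, 3, 3)
  expect_equal(weighted_kappa(xx, yy, range = c(1L, 3L)), 2 / 3)
  expect_equal(weighted_kappa(xx, yy, range = c(1L, 3L)),
               kappa_oracle(xx, yy, range = c(1L, 3L)))

  # chance-agreement limit under random pairing
  set.seed(14)
  a <- sample(1:5, 4000, replace = TRUE, prob = c(1, 2, 3, 2, 1))
  b <- sample(a)
  expect_lt(abs(weighted_kappa(a, b)), 0.05)
})

test_that("weighted kappa is symmetric and invariant to order-preserving shifts", {
  set.seed(6)
  for (rep in 1:20) {
    p <- random_pair_from_table(5, 80)
    k1 <- weighted_kappa(p$x, p$y)
    expect_equal(k1, weighted_kappa(p$y, p$x))
    # shift categories and declared range together
    expect_equal(k1, weighted_kappa(p$x + 3L, p$y + 3L, range = c(4L, 8L)))
  }
})

test_that("kappa handles missing and degenerate input", {
  expect_true(is.na(weighted_kappa(c(1, NA), c(NA, 2))))      # no complete pairs
  expect_true(is.na(weighted_kappa(rep(2, 10), rep(2, 10))))  # constant joint
  x <- c(1, 2, 3, NA, 5); y <- c(1, 2, 3, 4, NA)
  expect_equal(weighted_kappa(x, y), weighted_kappa(x[1:3], y[1:3]))
})

test_that("kappa interpretation follows the agreement bands", {
  expect_equal(interpret_kappa(0.83), "almost perfect")
  expect_equal(interpret_kappa(0.46), "moderate")
  expect_equal(interpret_kappa(0.205), "fair")  # rounds to 0.21
  expect_equal(interpret_kappa(c(-0.3, 0, 0.20, 0.21, 0.61, 0.80, 1)),
               c("poor", "slight", "slight", "fair", "substantial",
                 "substantial", "almost perfect"))
})

test_that("straight-lining rules evaluate per-battery constancy", {
  cb <- default_codebook()
  co <- generate_cohort(persona_config(n = 6, seed = 2, persona_mix = c(
    attentive = 1, straightliner = 0, speeder = 0, misrepresenter = 0,
    copier = 0), incomplete_rate = 0, miss_rate = 0))
  resp <- co$responses
  items <- setdiff(names(resp), "respondent_id")

  resp[1, items] <- 4L                          # constant everywhere
  for (bi in seq_along(cb$batteries)) {         # differing constants per set
    resp[2, cb$batteries[[bi]]$items] <- (bi - 1L) %% 5L + 1L
    resp[3, cb$batteries[[bi]]$items] <- (bi - 1L) %% 5L + 1L
  }
  resp[3, cb$batteries$fatigue$items] <- c(1L, 2L, 2L, 2L)  # one set breaks
  resp[4, items] <- 4L
  resp[4, "pf1"] <- NA                          # missing item in a set

  flags <- straightline_all_sets(resp, cb$batteries)
  expect_true(flags[1])
  expect_true(flags[2])   # rule is per-set constancy, constants may differ
  expect_false(flags[3])
  expect_false(flags[4])  # incomplete battery is never flagged
})

test_that("battery rules respect the allowed category", {
  cb <- default_codebook()
  resp <- data.frame(respondent_id = c("a", "b", "c", "d"))
  for (it in cb$items) resp[[it]] <- c(5L, 2L, 3L, 4L)
  pf <- straightline_battery(resp, cb$batteries$physical_function6)
  expect_equal(pf, c(FALSE, TRUE, TRUE, TRUE))  # all-5 allowed on this set
  s1 <- straightline_battery(resp, cb$batteries$sleep_set1)
  expect_equal(s1, c(TRUE, TRUE, FALSE, TRUE))  # all-3 allowed on sleep sets
})

test_that("mean root of pairs matches its stated formula", {
  resp <- data.frame(respondent_id = c("a", "b", "c", "d"),
                     s1 = c(2L, 1L, 1L, 1L), s2 = c(2L, 5L, 5L, NA),
                     s3 = c(2L, 1L, NA, NA))
  rp <- mean_root_of_pairs(resp, c("s1", "s2", "s3"))
  expect_equal(rp[[1]], 1)                       # constant responses
  expect_equal(rp[[2]], 1 / 3)                   # (1,5,1): 1 - (4/3)/2
  expect_equal(rp[[3]], 0)                       # single maximal pair
  expect_true(is.na(rp[[4]]))                    # fewer than 2 answered

  # spread monotonicity: tightening the same battery raises the score
  tight <- data.frame(respondent_id = "x", s1 = 3L, s2 = 3L, s3 = 4L)
  wide <- data.frame(respondent_id = "x", s1 = 1L, s2 = 3L, s3 = 5L)
  expect_gt(mean_root_of_pairs(tight, c("s1", "s2", "s3"))[[1]],
            mean_root_of_pairs(wide, c("s1", "s2", "s3"))[[1]])
})

test_that("planted straight-liners score higher on mean root of pairs", {
  co <- std_cohort()
  cb <- co$config$codebook
  rp <- mean_root_of_pairs(co$responses, cb$batteries$sleep_set1$items)
  sl <- co$truth$persona == "straightliner"
  at <- co$truth$persona == "attentive"
  expect_gt(mean(rp[sl], na.rm = TRUE), mean(rp[at], na.rm = TRUE))
  expect_equal(mean(rp[sl], na.rm = TRUE), 1)  # exact plants are constant
})

test_that("removing fake endorsers cannot raise the straight-lining rate", {
  # misrepresenters generated as partial sleep straight-liners
  cfg <- persona_config(n = 2500, misrep_straightline_prob = 0.4, seed = 55)
  co <- generate_cohort(cfg)
  scr <- build_analytic(co$responses, co$durations, co$endorsements)
  cb <- cfg$codebook
  sleep_flag <- function(resp) {
    mean(straightline_battery(resp, cb$batteries$sleep_set1) |
           straightline_battery(resp, cb$batteries$sleep_set2))
  }
  nofake <- scr$analytic[
    scr$analytic$respondent_id %in%
      scr$flags$respondent_id[scr$flags$in_analytic & !scr$flags$fake_endorser], ]
  expect_lte(sleep_flag(nofake), sleep_flag(scr$analytic))
})

test_that("Winsorized burden caps at the 97.5th percentile", {
  b <- winsorized_burden(rep(600, 12))
  expect_equal(b$mean, 10)            # minutes
  expect_equal(b$median, 10)
  expect_equal(b$sd, 0)

  x <- c(1:39, 1000)
  cap <- percentile_oracle(x, 0.975)
  b2 <- winsorized_burden(x, units = "seconds")
  expect_equal(b2$max, cap)
  expect_equal(b2$mean, mean(pmin(x, cap)))

  # capping is a projection: under the estimated cap, a second application
  # changes nothing
  capped <- pmin(x, cap)
  expect_equal(pmin(capped, cap), capped)
  b3 <- winsorized_burden(capped, units = "seconds", cap = cap)
  expect_equal(b3$mean, b2$mean)
  expect_equal(b3$max, b2$max)
})

test_that("the metric bundle is internally consistent", {
  scr <- std_screened()
  co <- std_cohort()
  keep <- co$durations$respondent_id %in% scr$analytic$respondent_id
  m <- careless_metrics(scr$analytic, co$durations[keep, , drop = FALSE])
  expect_named(m$kappa, names(default_codebook()$pairs))
  for (k in m$kappa) {
    expect_true(k$kappa >= -1 && k$kappa <= 1)
    expect_identical(k$interpretation, interpret_kappa(k$kappa))
  }
  expect_equal(m$n, nrow(scr$analytic))
  expect_equal(m$complete_all_items$pct, 100 * m$complete_all_items$n / m$n)
  expect_true(m$burden$min <= m$burden$median &&
                m$burden$median <= m$burden$max)
})
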