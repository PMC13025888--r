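test_that("degenerate inputs give the closed-form exposure draw", {
  s <- make_constant_samples(20, 0.2)
  r <- make_constant_records(30, 100)
  d <- simulate_exposure_draws(s, r, age = "total",
                               config = mc_config(500, seed = 1))
  expect_equal(d$body_weight, 57)
  expect_true(all(abs(d$draws - 0.2 * 100 / 57) < 1e-12))
  expect_error(simulate_exposure_draws(s[0, ], r), "empty")
  expect_error(simulate_exposure_draws(s, r, age = "13_17"), "no consumption")
})

test_that("draws are seed-deterministic and linear in the fraction", {
  s <- make_lognormal_samples(200, -2, 0.8)
  r <- make_lognormal_records(300, 4, 0.5)
  cfg <- mc_config(2000, seed = 9)
  d1 <- simulate_exposure_draws(s, r, "18_59", fraction = 1, config = cfg)
  d2 <- simulate_exposure_draws(s, r, "18_59", fraction = 1, config = cfg)
  expect_identical(d1$draws, d2$draws)
  d3 <- simulate_exposure_draws(s, r, "18_59", fraction = 0.0583,
                                config = cfg)
  expect_equal(d3$draws, 0.0583 * d1$draws)
})

test_that("percentile at the TDI is the inclusive empirical CDF", {
  expect_equal(percentile_at_tdi(seq(0.01, 1, by = 0.01), 0.1), 10)
  expect_equal(percentile_at_tdi(rep(0.5, 40), 0.5), 100)
  expect_error(percentile_at_tdi(numeric(0), 0.1), "empty")
  expect_error(percentile_at_tdi(1:3, 0), "tdi")

  # monotone in the TDI and invariant to permutation
  set.seed(1)
  v <- rlnorm(500, -1, 1)
  ts <- c(0.01, 0.1, 0.5, 1, 5)
  ps <- vapply(ts, percentile_at_tdi, numeric(1), draws = v)
  expect_true(all(diff(ps) >= 0))
  expect_equal(percentile_at_tdi(sample(v), 0.5),
               percentile_at_tdi(v, 0.5))
})

test_that("resampled exposure recovers the product-lognormal law", {
  mu1 <- -2; s1 <- 0.5; mu2 <- 4; s2 <- 0.8; bw <- 62.1
  s <- make_lognormal_samples(5000, mu1, s1)
  r <- make_lognormal_records(5000, mu2, s2)
  n_it <- 10000
  d <- simulate_exposure_draws(s, r, "18_59", config = mc_config(n_it, seed = 5))
  tdi <- 0.1
  p_true <- 100 * prodln_cdf_at(tdi, mu1, s1, mu2, s2, bw)
  se <- 100 * sqrt(p_true / 100 * (1 - p_true / 100) / n_it)
  expect_lt(abs(percentile_at_tdi(d, tdi) - p_true), 3 * se)

  q <- 0.005
  q_true <- prodln_quantile(1 - q, mu1, s1, mu2, s2, bw)
  p_min_true <- 100 * tdi / q_true
  se_q <- sqrt(q * (1 - q) / n_it) /
    prodln_density(q_true, mu1, s1, mu2, s2, bw)
  se_pmin <- p_min_true * se_q / q_true
  expect_lt(abs(min_conversion_proportion(d, tdi, q) - p_min_true),
            3 * se_pmin)
})

test_that("minimum conversion proportion behaves as a reverse threshold", {
  expect_equal(min_conversion_proportion(rep(10, 100), 0.1), 1.0)
  expect_equal(min_conversion_proportion(rep(0.05, 100), 0.1), 100)
  expect_warning(p <- min_conversion_proportion(rep(0, 10), 0.1), "capped")
  expect_equal(p, 100)

  # antitone in the exposure scale: scaling draws by k divides p_min by k
  set.seed(3)
  v <- rlnorm(2000, 1, 0.5)
  expect_equal(min_conversion_proportion(3 * v, 0.1),
               min_conversion_proportion(v, 0.1) / 3)
  expect_error(min_conversion_proportion(v, 0.1, q = 0), "q must lie")
})

test_that("replicate confidence intervals are percentile intervals", {
  cfg <- mc_config(10, replicates = 50, seed = 2)
  ci_const <- replicate_confidence_interval(function(seed) 7, cfg)
  expect_equal(as.numeric(ci_const), c(7, 7))

  stat <- function(seed) mean(tindiet:::.with_seed(seed, rnorm(400)))
  ci <- replicate_confidence_interval(stat, cfg)
  vals <- attr(ci, "values")
  expect_lte(ci[["ci_low"]], median(vals))
  expect_gte(ci[["ci_high"]], median(vals))

  # width shrinks roughly as sqrt(n) for a mean-like statistic
  stat_n <- function(n) function(seed)
    mean(tindiet:::.with_seed(seed, rnorm(n)))
  cfg_many <- mc_config(10, replicates = 400, seed = 2)
  w50 <- diff(unname(replicate_confidence_interval(stat_n(50), cfg_many)))
  w200 <- diff(unname(replicate_confidence_interval(stat_n(200), cfg_many)))
  expect_equal(w50 / w200, sqrt(200 / 50), tolerance = 0.25)
})

test_that("reverse assessment orders categories by exposure magnitude", {
  # one category only: the total diet is that category
  s <- make_lognormal_samples(500, -1, 0.6)
  r <- make_lognormal_records(500, 4, 0.5, age_group = "18_59")
  rv1 <- reverse_assessment(s, r, config = mc_config(2000, 10, seed = 3))
  expect_equal(rv1$p_min[rv1$category == "fresh_aquatic"],
               rv1$p_min[rv1$category == "total_diet"])

  # two categories with stochastically ordered exposure: the larger one
  # needs the smaller conversion fraction
  s2 <- rbind(s, make_lognormal_samples(500, 1, 0.6, type_name = "Green Tea",
                                        category = "tea", lod = 0.008))
  r2 <- rbind(r, make_lognormal_records(500, 4, 0.5,
                                        type_name = "Green Tea"))
  rv2 <- reverse_assessment(s2, r2, config = mc_config(2000, 10, seed = 3))
  expect_lt(rv2$p_min[rv2$category == "tea"],
            rv2$p_min[rv2$category == "fresh_aquatic"])
  expect_true(all(rv2$p_min[rv2$category == "total_diet"] <=
                    rv2$p_min[rv2$category != "total_diet"]))
  expect_true(all(rv2$ci_low <= rv2$p_min & rv2$p_min <= rv2$ci_high))
})

test_that("percentile-at-TDI table is reproducible and CI-consistent", {
  sd <- simulate_study_data(n_per_age = 100, seed = 6)
  aq <- sd$samples[sd$samples$category == "fresh_aquatic", ]
  cfg <- mc_config(2000, replicates = 10, seed = 8)
  t1 <- tdi_percentile_table(aq, sd$records, ages = c("le6", "total"),
                             config = cfg)
  t2 <- tdi_percentile_table(aq, sd$records, ages = c("le6", "total"),
                             config = cfg)
  expect_identical(t1, t2)
  expect_true(all(t1$ci_low <= t1$percentile & t1$percentile <= t1$ci_high))
  expect_true(all(t1$percentile >= 0 & t1$percentile <= 100))
})
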