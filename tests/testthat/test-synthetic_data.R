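cs_fix <- zj_concentrations()
cq_fix <- zj_consumption()

test_that("concentration calibration reproduces detection rates and targets", {
  tuber <- cs_fix[cs_fix$type_name == "Tuber and Root Vegetables", ]
  sp <- calibrate_concentration_spec(tuber)
  expect_equal(sp$detect_prob, 72 / 239)

  # fully detected, degenerate quantiles -> a point distribution
  degen <- data.frame(category = "fresh_aquatic", type_name = "Fish",
                      n = 50, n_detect = 50, mean = 0.10, p50 = 0.10,
                      p95 = 0.10, iqr = 0, min = 0.10, max = 0.10,
                      lod = 0.004)
  spd <- calibrate_concentration_spec(degen)
  expect_equal(spd$log_sigma, 0)
  expect_equal(spd$log_mu, log(0.10))

  expect_error(calibrate_concentration_spec(transform(tuber, n = 0)), "n < 1")
  expect_error(calibrate_concentration_spec(transform(tuber, p50 = -1)),
               class = "tindiet_validation_error")
})

test_that("calibrated mixtures recover printed P50/P95 in large samples", {
  specs <- calibrate_concentration_specs(cs_fix)
  for (i in seq_len(nrow(specs))) {
    g <- generate_concentration_samples(specs[i, ], n = 100000, seed = 7)
    p95 <- brute_quantile(g$value, 0.95)
    t95 <- specs$target_p95[i]
    tol <- if (t95 < 0.05) 0.005 else 0.05 * t95
    expect_lt(abs(p95 - t95), tol + 1e-12, label = specs$type_name[i])
  }
})

test_that("concentration generation is deterministic with exact counts", {
  tuber <- calibrate_concentration_spec(
    cs_fix[cs_fix$type_name == "Tuber and Root Vegetables", ])
  g1 <- generate_concentration_samples(tuber, n = 239, seed = 11)
  g2 <- generate_concentration_samples(tuber, n = 239, seed = 11)
  expect_identical(g1, g2)
  expect_equal(sum(!g1$detected), 167)  # 239 - 72 detects
  expect_true(all(g1$value >= 0))
  expect_true(all(g1$value[!g1$detected] == 0.004 / 2))
  expect_true(all(g1$substituted == !g1$detected))
  g3 <- generate_concentration_samples(tuber, n = 239, seed = 12)
  expect_false(identical(g1$value, g3$value))      # order differs ...
  expect_identical(sort(g1$value), sort(g3$value)) # ... values do not
  expect_error(generate_concentration_samples(tuber, n = 0), "n must be")
})

test_that("raising log_mu shifts generated concentrations upward", {
  base <- calibrate_concentration_spec(cs_fix[cs_fix$type_name == "Fish", ])
  hi <- base
  hi$log_mu <- base$log_mu + 1
  m0 <- mean(generate_concentration_samples(base, n = 5000, seed = 3)$value)
  m1 <- mean(generate_concentration_samples(hi, n = 5000, seed = 3)$value)
  expect_gt(m1, m0)
})

test_that("consumption calibration solves the two-quantile lognormal", {
  row <- data.frame(type_name = "Fish", age_group = "18_59",
                    body_weight = 62.1, p50 = 100, p95 = 200)
  sp <- calibrate_consumption_spec(row)
  expect_equal(sp$zero_prob, 0)
  expect_equal(sp$log_mu, log(100))
  expect_equal(sp$log_sigma, log(2) / qnorm(0.95), tolerance = 1e-10)

  zero <- calibrate_consumption_spec(transform(row, p50 = 0, p95 = 0))
  expect_equal(zero$zero_prob, 1)

  half <- calibrate_consumption_spec(transform(row, p50 = 0, p95 = 150))
  expect_equal(half$zero_prob, 0.6)

  expect_error(calibrate_consumption_spec(transform(row, p50 = -5)),
               class = "tindiet_validation_error")
})

test_that("generated consumption reproduces quantiles and zero inflation", {
  row <- data.frame(type_name = "Fish", age_group = "18_59",
                    body_weight = 62.1, p50 = 80, p95 = 200)
  sp <- calibrate_consumption_spec(row)
  r <- generate_consumption_records(sp, n_per_age = 100000, seed = 5)
  expect_equal(brute_quantile(r$intake, 0.5), 80, tolerance = 0.05)

  row2 <- transform(row, p50 = 100, p95 = 200)
  r2 <- generate_consumption_records(calibrate_consumption_spec(row2),
                                     n_per_age = 10000, seed = 5)
  ratio <- brute_quantile(r2$intake, 0.95) / brute_quantile(r2$intake, 0.5)
  expect_equal(ratio, 2.0, tolerance = 0.05)

  # zero-median cell: exact zero count, P95 recovered
  row3 <- transform(row, p50 = 0, p95 = 150)
  r3 <- generate_consumption_records(calibrate_consumption_spec(row3),
                                     n_per_age = 10000, seed = 5)
  expect_equal(sum(r3$intake == 0), 6000)
  expect_equal(brute_quantile(r3$intake, 0.95), 150, tolerance = 150 * 0.05)

  r4 <- generate_consumption_records(
    calibrate_consumption_spec(transform(row, p50 = 0, p95 = 0)), 50, seed = 2)
  expect_true(all(r4$intake == 0))

  sp_all <- calibrate_consumption_specs(cq_fix[cq_fix$age_group == "le6", ])
  a <- generate_consumption_records(sp_all, 200, seed = 9)
  b <- generate_consumption_records(sp_all, 200, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$intake >= 0))
  expect_true(all(a$body_weight == 19.9))
  expect_error(generate_consumption_records(sp_all, 0), "n_per_age")
})

test_that("simulate_study_data closes the calibrate-generate-summarize loop", {
  sd <- simulate_study_data(n_per_age = 100, seed = 4)
  expect_equal(nrow(sd$samples), sum(cs_fix$n))
  expect_equal(nrow(sd$records), 25 * 5 * 100)
  resum <- summarize_concentrations_by_item(sd$samples)
  expect_equal(resum$n, cs_fix$n)
  expect_equal(resum$n_detect, cs_fix$n_detect)
})
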