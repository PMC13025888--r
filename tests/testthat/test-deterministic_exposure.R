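grid_fix <- scenario_exposure_table()

test_that("the intake formula reproduces published anchor cells", {
  expect_equal(round(compute_edi(80.73, 40, 62.1), 2), 52.00)
  expect_equal(round(compute_edi(0.50, 100, 19.9), 2), 2.51)
  expect_equal(compute_edi(5, 0, 60), 0)
  expect_error(compute_edi(1, 1, 0), "bw must be")
  expect_error(compute_edi(-1, 1, 60), ">= 0")
})

test_that("the intake formula is bilinear in its factors", {
  expect_equal(compute_edi(2 * 0.3, 50, 60), 2 * compute_edi(0.3, 50, 60))
  expect_equal(compute_edi(0.3, 2 * 50, 60), 2 * compute_edi(0.3, 50, 60))
  expect_equal(compute_edi(0.3, 50, 2 * 60), compute_edi(0.3, 50, 60) / 2)
})

test_that("scenario grid covers all cells and matches the aquatic anchors", {
  expect_equal(nrow(grid_fix$cells), 25 * 5 * 4)
  aq <- scenario_exposure_table(
    zj_concentrations()[zj_concentrations()$category == "fresh_aquatic", ])
  cC <- aq$totals[aq$totals$scenario == "C", ]
  got <- setNames(round(cC$sum_edi, 2), cC$age_group)
  expect_equal(got[c("le6", "7_12", "13_17", "18_59", "ge60")],
               c(le6 = 1.60, `7_12` = 0.94, `13_17` = 0.83,
                 `18_59` = 0.78, ge60 = 0.70))
})

test_that("scenario grid flags missing item-age pairings", {
  cq <- zj_consumption()
  drop <- !(cq$type_name == "Fish" & cq$age_group == "le6")
  err <- expect_error(scenario_exposure_table(consumption = cq[drop, ]),
                      class = "tindiet_validation_error")
  expect_match(conditionMessage(err), "Fish/le6")
})

test_that("zero consumption yields zero exposure everywhere", {
  cq0 <- zj_consumption()
  cq0$p50 <- 0
  cq0$p95 <- 0
  g <- scenario_exposure_table(consumption = cq0)
  expect_true(all(g$cells$edi == 0))
  expect_true(all(g$totals$sum_edi == 0))
})

test_that("exposure is monotone across the scenario grid", {
  # quantile monotonicity needs valid (non-inverted) consumption quantiles
  cq <- load_consumption_quantiles(fixture_path("consumption.csv"),
                                   on_inverted = "swap")
  g <- scenario_exposure_table(consumption = cq)$cells
  w <- reshape(g[, c("type_name", "age_group", "scenario", "edi")],
               idvar = c("type_name", "age_group"), timevar = "scenario",
               direction = "wide")
  expect_true(all(w$edi.A <= w$edi.B + 1e-12))
  expect_true(all(w$edi.A <= w$edi.C + 1e-12))
  expect_true(all(w$edi.B <= w$edi.D + 1e-12))
  expect_true(all(w$edi.C <= w$edi.D + 1e-12))
})

test_that("total hazard sums per-item quotients against the reference", {
  cells <- grid_fix$cells[grid_fix$cells$age_group == "18_59" &
                            grid_fix$cells$scenario == "D", ]
  h <- total_hazard(cells, 300)
  expect_equal(h$thq, sum(h$per_item_hq))
  expect_equal(h$thq, h$sum_edi / 300)
  expect_false(h$exceeds)
  expect_equal(round(h$thq, 4), 0.2176, tolerance = 2e-3)

  aq <- cells[cells$category == "fresh_aquatic", ]
  rest <- cells[cells$category != "fresh_aquatic", ]
  expect_equal(total_hazard(aq, 300)$thq + total_hazard(rest, 300)$thq,
               h$thq)  # THQ is additive over disjoint item sets

  e <- total_hazard(cells[0, ], 0.1)
  expect_equal(e$sum_edi, 0)
  expect_equal(e$thq, 0)
  expect_error(total_hazard(cells, -1), "positive")
  expect_error(total_hazard(grid_fix$cells, 300),
               class = "tindiet_validation_error")  # mixed groups
})

test_that("category shares normalise to one and handle degenerate totals", {
  shares <- category_contributions(grid_fix$cells)
  tot <- aggregate(share ~ age_group + scenario,
                   shares[shares$defined, ], sum)
  expect_true(all(abs(tot$share - 1) < 1e-12))

  one_cat <- grid_fix$cells[grid_fix$cells$category == "canned" &
                              grid_fix$cells$age_group == "18_59" &
                              grid_fix$cells$scenario == "D", ]
  s1 <- category_contributions(one_cat)
  expect_equal(s1$share, 1)

  # the dominant canned-fruit cell carries ~79.6% of the adult scenario-D total
  d <- shares[shares$age_group == "18_59" & shares$scenario == "D", ]
  frt <- grid_fix$cells[grid_fix$cells$type_name ==
                          "Canned Fruits and Fruit Products" &
                          grid_fix$cells$age_group == "18_59" &
                          grid_fix$cells$scenario == "D", "edi"]
  expect_equal(frt / sum(d$sum_edi), 0.796, tolerance = 0.005)

  zero <- grid_fix$cells[1:4, ]
  zero$edi <- 0
  s0 <- category_contributions(zero)
  expect_true(all(!s0$defined))
  expect_true(all(is.na(s0$share)))
})

test_that("organotin screening scales linearly in the assumed fraction", {
  full <- organotin_scenario_assessment(reproduce_table4 = TRUE)
  frac <- organotin_scenario_assessment()  # default 5.83%
  expect_equal(frac$sum_edi, 0.0583 * full$sum_edi)
  expect_equal(frac$thq, 0.0583 * full$thq)

  cC <- full[full$scenario == "C" & full$age_group == "le6", ]
  expect_equal(round(cC$sum_edi, 2), 1.60)
  expect_equal(round(cC$thq, 1), 16)
  expect_true(cC$exceeds)

  tiny <- organotin_scenario_assessment(fraction = 1e-9)
  expect_true(all(tiny$thq < 1e-6))
  expect_error(organotin_scenario_assessment(fraction = 2), "fraction")
  expect_error(organotin_scenario_assessment(tdi = 0), "tdi")
})
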