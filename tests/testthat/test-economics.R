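test_that("discount factors follow (1+r)^-t", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0, 17), 1)
  expect_equal(discount_factor(0.03, 2), 0.942595909134, tolerance = 1e-12)
  expect_error(discount_factor(-0.01, 1))
})

test_that("non-medical state costs assemble from the input table", {
  ps <- base_params()
  # complication states carry their literature annual totals
  expect_equal(annual_nonmedical_cost(ps, "STROKE", "surgery", 5), 63159.45)
  expect_equal(annual_nonmedical_cost(ps, "CKD", "nonsurgery", 2), 168863)
  expect_equal(annual_nonmedical_cost(ps, "MI_FIRST_YEAR", "surgery", 1),
               annual_nonmedical_cost(ps, "MI_POST", "surgery", 5))
  # with zero visit frequencies, a later-cycle remission year is the sum of
  # the three annual items: 4,933.46 + 14,448.98 + 2,348.98
  vp0 <- list(op_t2dm = 0, op_remission = 0, ip = 0)
  expect_equal(annual_nonmedical_cost(ps, "REMISSION", "nonsurgery", 2, vp0),
               21731.42)
  # first-year-only items (accommodation + renovation) attach to cycle 1
  expect_equal(annual_nonmedical_cost(ps, "REMISSION", "nonsurgery", 1, vp0) -
                 annual_nonmedical_cost(ps, "REMISSION", "nonsurgery", 2, vp0),
               5598.86 + 1159.09)
  # outside-hospital treatment is arm-specific in the non-remission state
  expect_equal(annual_nonmedical_cost(ps, "OBESE_T2DM", "surgery", 2, vp0) -
                 annual_nonmedical_cost(ps, "OBESE_T2DM", "nonsurgery", 2, vp0),
               10645.88 - 1396.77)
  # everything zeroed gives zero
  ps0 <- ps
  nm <- ps0$specs$role == "cost_nonmedical"
  ps0$specs$mean[nm] <- 0
  expect_equal(annual_nonmedical_cost(ps0, "OBESE_T2DM", "surgery", 2, vp0), 0)
  expect_error(annual_nonmedical_cost(ps, "OBESE_T2DM", "surgery", 1,
                                      list(op_t2dm = 4)),
               "missing frequencies")
})

test_that("medical state costs are year-indexed where the table splits them", {
  ps <- base_params()
  expect_equal(annual_medical_cost(ps, "OBESE_T2DM", "surgery", 1), 36536.72)
  expect_equal(annual_medical_cost(ps, "OBESE_T2DM", "surgery", 2), 30114.01)
  expect_equal(annual_medical_cost(ps, "OBESE_T2DM", "surgery", 7), 30589.87)
  expect_equal(annual_medical_cost(ps, "OBESE_T2DM", "nonsurgery", 7), 30504.77)
  expect_equal(annual_medical_cost(ps, "MI_FIRST_YEAR", "surgery", 3), 119212.12)
  expect_equal(annual_medical_cost(ps, "MI_POST", "surgery", 4), 28612.87)
})

test_that("accumulation discounts occupancy-weighted values", {
  ps <- base_params(utils::modifyList(default_run_config(),
                                      list(discount_rate = 0)))
  # one-cycle toy: all mass stays obese for a year -> 0.83 QALYs
  occ <- matrix(0, 2, 8, dimnames = list(0:1, health_states()))
  occ[, "OBESE_T2DM"] <- 1
  toy <- structure(list(occupancy = occ, ages = 40:41, arm = "nonsurgery"),
                   class = "cohort_trace")
  vals <- state_value_table(ps, "nonsurgery", "payer", 1)
  out <- accumulate_outcomes(toy, vals, rate = 0)
  expect_equal(out$qaly, 0.83)
  expect_equal(out$ly, 1)
  expect_equal(out$cost, 30504.77)
  # utilities of 1 make QALYs equal life years exactly
  ps1 <- set_param_values(ps, c(u_t2dm = 1, u_remission = 1, u_mi = 1,
                                u_stroke = 1, u_chf = 1, u_ckd = 1))
  tr <- run_cohort("surgery", ps1, base_lt())
  v1 <- state_value_table(ps1, "surgery", "payer", nrow(tr$occupancy) - 1)
  o1 <- accumulate_outcomes(tr, v1, 0.03)
  expect_equal(o1$qaly, o1$ly, tolerance = 1e-12)
  # an extreme discount rate leaves only the cycle-0 one-time cost
  vals_s <- state_value_table(ps, "surgery", "payer", 1)
  out_inf <- accumulate_outcomes(toy, vals_s, rate = 1e12)
  expect_equal(out_inf$cost, vals_s$one_time, tolerance = 1e-6)
})

test_that("strategy comparison classifies dominance and the threshold", {
  mk <- function(cost, qaly) {
    structure(list(arm = "x", cost_payer = cost, cost_societal = cost,
                   ly = qaly, qaly = qaly), class = "econ_outcome")
  }
  # arithmetic on the published base-case table values
  r <- compare_strategies(mk(676658.39, 16.08), mk(574683.38, 14.78), 160000,
                          "payer")
  expect_equal(r$icer_qaly, 78442.3153846, tolerance = 1e-9)
  expect_equal(r$verdict, "ICER")
  expect_true(r$cost_effective)
  # cheaper and more effective dominates
  expect_equal(compare_strategies(mk(99, 1.1), mk(100, 1.0), 1e5)$verdict,
               "dominant")
  expect_equal(compare_strategies(mk(101, 0.9), mk(100, 1.0), 1e5)$verdict,
               "dominated")
  # the threshold boundary is inclusive
  b <- compare_strategies(mk(160000, 2), mk(0, 1), 160000)
  expect_true(b$cost_effective)
  # equal effectiveness: verdict by cost sign, ICER undefined
  eq <- compare_strategies(mk(101, 1), mk(100, 1), 1e5)
  expect_equal(eq$verdict, "dominated")
  expect_true(is.na(eq$icer_qaly))
})

test_that("full base case keeps the expected orderings", {
  res <- run_cea(base_params(), base_lt())
  s <- res$surgery; n <- res$nonsurgery
  expect_lte(s$qaly, s$ly)
  expect_lte(n$qaly, n$ly)
  expect_gte(s$cost_societal, s$cost_payer)
  expect_gte(n$cost_societal, n$cost_payer)
  expect_gt(s$cost_payer, n$cost_payer)
  expect_gt(s$cost_societal, n$cost_societal)
  expect_gt(s$qaly, n$qaly)
  expect_lt(res$societal$icer_qaly, res$payer$icer_qaly)
  expect_equal(dim(res$table), c(4L, 7L))
})

test_that("removing the remission benefit makes surgery dominated", {
  ps <- set_param_values(base_params(), c(
    p_remission_bs_y1 = 0.0156, p_remission_bs_y2 = 0.0156,
    p_remission_bs_y3 = 0.0156, p_remission_bs_y4plus = 0.0156,
    p_relapse_bs = 0.0708))
  res <- run_cea(ps, base_lt())
  expect_equal(res$payer$verdict, "dominated")
})

test_that("half-cycle correction adds roughly half a starting year", {
  cfg <- utils::modifyList(default_run_config(), list(half_cycle = TRUE))
  ly_h <- evaluate_arm("surgery", base_params(cfg), base_lt())$ly
  ly <- evaluate_arm("surgery", base_params(), base_lt())$ly
  expect_gt(ly_h, ly)
  expect_lt(ly_h - ly, 0.6)
})

test_that("discounting only shrinks outcomes", {
  cfg0 <- utils::modifyList(default_run_config(), list(discount_rate = 0))
  o0 <- evaluate_arm("nonsurgery", base_params(cfg0), base_lt())
  o3 <- evaluate_arm("nonsurgery", base_params(), base_lt())
  expect_gte(o0$ly, o3$ly)
  expect_gte(o0$qaly, o3$qaly)
  expect_gte(o0$cost_payer, o3$cost_payer)
})
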