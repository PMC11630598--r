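test_that("transition matrices are row-stochastic with published entries", {
  ps <- base_params()
  lt <- base_lt()
  for (arm in c("surgery", "nonsurgery")) {
    for (cyc in c(1, 2, 3, 4, 10)) {
      M <- build_matrix(arm, cyc, 40 + cyc - 1, ps, lt)
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(rowSums(M), stats::setNames(rep(1, 8), health_states()),
                   tolerance = 1e-12)
      expect_equal(M["DEAD", "DEAD"], 1)
      expect_equal(M["MI_FIRST_YEAR", "MI_FIRST_YEAR"], 0)  # tunnel
    }
  }
  # cycle-indexed remission in the surgery arm; constant in the comparator
  expect_equal(build_matrix("surgery", 1, 40, ps, lt)["OBESE_T2DM", "REMISSION"],
               0.4333)
  expect_equal(build_matrix("surgery", 2, 41, ps, lt)["OBESE_T2DM", "REMISSION"],
               0.2941)
  expect_equal(build_matrix("surgery", 3, 42, ps, lt)["OBESE_T2DM", "REMISSION"],
               0.0833)
  expect_equal(build_matrix("surgery", 9, 48, ps, lt)["OBESE_T2DM", "REMISSION"],
               0.0156)
  expect_equal(build_matrix("nonsurgery", 1, 40, ps, lt)["OBESE_T2DM", "REMISSION"],
               0.0156)
  # complication fatality combines with background mortality multiplicatively
  d <- background_mortality(lt, 40, rr = ps$config$rr_mortality)
  expect_equal(build_matrix("surgery", 1, 40, ps, lt)["CHF", "DEAD"],
               1 - (1 - d) * (1 - 0.325))
})

test_that("an overfull row raises a misspecification error", {
  ps <- set_param_values(base_params(), c(p_remission_bs_y1 = 0.95,
                                          p_t2dm_ckd = 0.1))
  expect_error(build_matrix("surgery", 1, 40, ps, base_lt()),
               "misspecification")
})

test_that("cohort propagation conserves mass and absorbs into death", {
  ps <- base_params()
  lt <- base_lt()
  for (arm in c("surgery", "nonsurgery")) {
    tr <- run_cohort(arm, ps, lt)
    expect_equal(unname(tr$occupancy[1, ]), c(1, rep(0, 7)))
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
    expect_true(all(diff(tr$occupancy[, "DEAD"]) >= -1e-12))
    expect_equal(tr$ages[1], 40)
  }
})

test_that("with complications and death off, the engine matches the
           two-state closed form", {
  a <- 0.0156; b <- 0.0708
  ps <- two_state_params(a, b)
  tr <- run_cohort("nonsurgery", ps, zero_lt())
  for (n in 1:50) {
    expect_equal(tr$occupancy[n + 1, "REMISSION"],
                 two_state_closed_form(a, b, n),
                 tolerance = 1e-10)
  }
})

test_that("two cycles of hand arithmetic match the trace", {
  # constant remission 0.4333, relapse 0.0107, nothing else
  ps <- two_state_params(0.4333, 0.0107)
  tr <- run_cohort("surgery", ps, zero_lt())
  r1 <- 0.4333
  r2 <- r1 * (1 - 0.0107) + (1 - r1) * 0.4333  # = 0.6742148
  expect_equal(tr$occupancy[2, "REMISSION"], r1, tolerance = 1e-12)
  expect_equal(tr$occupancy[3, "REMISSION"], 0.6742148, tolerance = 1e-10)
  expect_equal(tr$occupancy[3, "OBESE_T2DM"], 1 - r2, tolerance = 1e-12)
})

test_that("state occupancy summary totals undiscounted life expectancy", {
  ps <- base_params()
  lt <- base_lt()
  s_surg <- state_occupancy_summary(run_cohort("surgery", ps, lt))
  s_non <- state_occupancy_summary(run_cohort("nonsurgery", ps, lt))
  # surgery arm lives at least as long (remission has no mortality benefit,
  # but fewer complication-years mean fewer excess deaths)
  expect_gte(attr(s_surg, "life_years"), attr(s_non, "life_years"))
  # an immediately absorbing toy accrues no living years: with certain
  # death in the first cycle, end-of-cycle accounting counts zero
  ps0 <- two_state_params(0, 0)
  lt1 <- life_table(data.frame(age = 0:100, q = rep(1, 101)), rr = 1)
  s <- state_occupancy_summary(run_cohort("surgery", ps0, lt1))
  expect_equal(attr(s, "life_years"), 0)
})

test_that("raising death probabilities never lengthens life", {
  cfg <- default_run_config()
  ps <- base_params(cfg)
  lt <- base_lt()
  ly <- function(p) attr(state_occupancy_summary(run_cohort("surgery", p, lt)),
                         "life_years")
  base_ly <- ly(ps)
  deadlier <- set_param_values(ps, c(p_death_mi = 0.064,
                                     p_death_stroke = 0.0988,
                                     p_death_chf = 0.65, p_death_ckd = 0.2196))
  deadlier$config$rr_mortality <- 2 * cfg$rr_mortality
  expect_lte(ly(deadlier), base_ly)
})

test_that("traces export to a tidy data frame", {
  tr <- run_cohort("surgery", base_params(), base_lt())
  df <- as.data.frame(tr)
  expect_equal(names(df)[1:3], c("cycle", "age", "arm"))
  expect_equal(nrow(df), nrow(tr$occupancy))
  expect_equal(df$age, df$cycle + 40)
})
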