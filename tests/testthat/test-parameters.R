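test_that("the packaged parameter table loads and validates", {
  ps <- base_params()
  expect_s3_class(ps, "param_set")
  expect_true(all(REQUIRED_PARAMS %in% ps$specs$name))
  expect_equal(param_value(ps, "p_remission_bs_y1"), 0.4333)
  expect_equal(param_spec(ps, "p_remission_bs_y1")$se, 0.13)
  expect_equal(param_value(ps, "c_surgery"), 279899.62)
  expect_equal(param_value(ps, "u_remission"), 0.97)
})

test_that("loading rejects malformed parameter tables", {
  # missing required parameter, named in the error
  p1 <- write_param_fixture(function(df) df[df$name != "c_surgery", ])
  expect_error(load_parameters(p1), "c_surgery")
  # duplicate name
  p2 <- write_param_fixture(function(df) rbind(df, df[1, ]))
  expect_error(load_parameters(p2), "duplicate")
  # beta probability out of range
  p3 <- write_param_fixture(function(df) {
    df$mean[df$name == "p_t2dm_mi"] <- 1.2
    df
  })
  expect_error(load_parameters(p3), "outside \\[0, 1\\]")
  # beta variance infeasible
  p4 <- write_param_fixture(function(df) {
    df$se[df$name == "p_t2dm_mi"] <- 0.9
    df
  })
  expect_error(load_parameters(p4), "infeasible")
})

test_that("parameter values can be looked up and replaced", {
  ps <- base_params()
  ps2 <- set_param_values(ps, c(u_t2dm = 0.5, c_surgery = 1000))
  expect_equal(param_value(ps2, "u_t2dm"), 0.5)
  expect_equal(param_value(ps2, "c_surgery"), 1000)
  expect_equal(param_value(ps, "u_t2dm"), 0.83)  # original untouched
  expect_error(param_value(ps, "no_such_param"), "unknown")
  expect_error(set_param_values(ps, c(no_such_param = 1)), "unknown")
})

test_that("beta method of moments reproduces its inputs", {
  # frozen from the closed-form formulas alpha = m*k, beta = (1-m)*k with
  # k = m*(1-m)/s^2 - 1
  sh <- beta_from_moments(0.0156, 0.0047)
  expect_equal(unname(sh), c(10.8292883658, 683.355863287), tolerance = 1e-9)
  # round trip through the beta moment formulas
  m <- sh[[1]] / sum(sh)
  v <- sh[[1]] * sh[[2]] / (sum(sh)^2 * (sum(sh) + 1))
  expect_equal(m, 0.0156, tolerance = 1e-12)
  expect_equal(sqrt(v), 0.0047, tolerance = 1e-12)
  # near-symmetric limit: se -> 0 keeps alpha/beta at the mean's odds
  sh <- beta_from_moments(0.5, 1e-6)
  expect_equal(sh[[1]] / sh[[2]], 1, tolerance = 1e-9)
  # high-mean utility case stays feasible and round-trips
  sh <- beta_from_moments(0.97, 0.01)
  expect_equal(sh[[1]] / sum(sh), 0.97, tolerance = 1e-12)
  expect_error(beta_from_moments(0.5, 0.6, name = "p_x"), "p_x")
})

test_that("gamma method of moments reproduces its inputs", {
  sh <- gamma_from_moments(30504.77, 1066.81)
  expect_equal(unname(sh), c(817.63853929, 37.3083808237), tolerance = 1e-9)
  expect_equal(sh[["shape"]] * sh[["scale"]], 30504.77, tolerance = 1e-9)
  expect_equal(sqrt(sh[["shape"]]) * sh[["scale"]], 1066.81, tolerance = 1e-9)
  # se = mean gives an exponential
  expect_equal(gamma_from_moments(4933.46, 4933.46)[["shape"]], 1)
  expect_error(gamma_from_moments(0, 1), "positive")
})

test_that("moment round-trips hold for every packaged parameter", {
  ps <- base_params()
  for (i in seq_len(nrow(ps$specs))) {
    sp <- ps$specs[i, ]
    if (sp$se == 0) next
    if (sp$family == "beta") {
      sh <- beta_from_moments(sp$mean, sp$se, sp$name)
      expect_equal(sh[[1]] / sum(sh), sp$mean, tolerance = 1e-12)
    } else {
      sh <- gamma_from_moments(sp$mean, sp$se, sp$name)
      expect_equal(sh[["shape"]] * sh[["scale"]], sp$mean, tolerance = 1e-12)
    }
  }
})

test_that("sampling recovers the stated moments and is seed-stable", {
  ps <- base_params()
  for (nm in c("c_surgery", "p_remission_bs_y1", "u_remission")) {
    sp <- param_spec(ps, nm)
    x <- sample_parameter(sp, 10000, seed = 99)
    expect_lt(abs(mean(x) - sp$mean), 4 * sp$se / sqrt(10000))
    expect_lt(abs(stats::sd(x) - sp$se), 4 * sp$se / sqrt(2 * 10000))
  }
  sp <- param_spec(ps, "c_surgery")
  expect_identical(sample_parameter(sp, 50, seed = 7),
                   sample_parameter(sp, 50, seed = 7))
})

test_that("zero-SE parameters are sampled as fixed, with a message", {
  ps <- base_params()
  sp <- param_spec(ps, "c_surgery")
  sp$se <- 0
  expect_message(x <- sample_parameter(sp, 5, seed = 1), "fixed")
  expect_identical(x, rep(sp$mean, 5))
  expect_equal(unname(parameter_interval(sp)), rep(sp$mean, 2))
})

test_that("background mortality applies the rate ratio with a cap", {
  lt <- life_table(data.frame(age = 0:100, q = rep(0.01, 101)), rr = 1)
  expect_equal(background_mortality(lt, 50), 0.01)
  lt3 <- life_table(data.frame(age = 0:100, q = rep(0.5, 101)), rr = 3)
  expect_equal(background_mortality(lt3, 50), 1)  # min(1, 1.5)
  # above-range ages clamp to the last row with a warning
  expect_warning(q <- background_mortality(lt, 140), "clamped")
  expect_equal(q, 0.01)
  expect_error(background_mortality(lt, -1), "below")
})

test_that("the packaged life table is monotone and plausible", {
  lt <- base_lt(rr = 1)
  q <- background_mortality(lt, 0:100)
  expect_true(all(diff(q) >= 0))
  expect_lt(background_mortality(lt, 40), background_mortality(lt, 80))
  expect_equal(life_expectancy(lt, 0), 75, tolerance = 0.01)
  le40 <- life_expectancy(lt, 40)
  expect_gt(le40, 30)
  expect_lt(le40, 45)
})
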