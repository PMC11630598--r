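# Shared fixtures: the packaged parameter set and life table, and reduced
# variants used by the closed-form oracles.

base_params <- function(config = default_run_config()) {
  load_parameters(config = config)
}

base_lt <- function(rr = default_run_config()$rr_mortality) {
  default_life_table(rr = rr)
}

# A life table with zero mortality at every age.
zero_lt <- function() life_table(data.frame(age = 0:120, q = 0), rr = 1)

# Parameter set reduced to a two-state remission/relapse chain: every
# complication and death probability zeroed, constant remission a and
# relapse b in both arms. Used against the closed-form occupancy
# r_n = pi + (r_0 - pi) * (1 - a - b)^n with pi = a / (a + b).
two_state_params <- function(a, b, config = default_run_config()) {
  ps <- base_params(config)
  zero <- c("p_t2dm_mi", "p_t2dm_stroke", "p_t2dm_chf", "p_t2dm_ckd",
            "p_remission_mi", "p_remission_stroke", "p_remission_chf",
            "p_remission_ckd", "p_death_mi", "p_death_stroke",
            "p_death_chf", "p_death_ckd")
  ps <- set_param_values(ps, stats::setNames(rep(0, length(zero)), zero))
  set_param_values(ps, c(
    p_remission_bs_y1 = a, p_remission_bs_y2 = a, p_remission_bs_y3 = a,
    p_remission_bs_y4plus = a, p_remission_nonbs = a,
    p_relapse_bs = b, p_relapse_nonbs = b))
}

two_state_closed_form <- function(a, b, n, r0 = 0) {
  pi <- a / (a + b)
  pi + (r0 - pi) * (1 - a - b)^n
}

# Write a modified copy of the packaged parameter CSV and return its path.
write_param_fixture <- function(transform) {
  df <- utils::read.csv(system.file("extdata", "parameters.csv",
                                    package = "bariaCEA"),
                        comment.char = "#",
                        colClasses = c(cycle_scope = "character"))
  df <- transform(df)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
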