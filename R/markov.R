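# Markov cohort engine: cycle-indexed transition matrices per treatment arm
# and closed-cohort propagation from entry age over the lifetime horizon.
#
# Engine states. The clinical model has seven states (obese with T2DM, DM
# remission, MI, stroke, CHF, CKD, dead); MI is split into a first-year
# tunnel and a post-year state so the first-year MI treatment cost can
# differ from later years.
HEALTH_STATES <- c("OBESE_T2DM", "REMISSION", "MI_FIRST_YEAR", "MI_POST",
                   "STROKE", "CHF", "CKD", "DEAD")
LIVING_STATES <- setdiff(HEALTH_STATES, "DEAD")

#' Engine health states
#'
#' @return Character vector of the eight engine states, in matrix order.
#' @export
health_states <- function() HEALTH_STATES

# Probability of moving from obese-with-T2DM to remission in a given cycle.
# The surgery arm's remission probability is indexed by years since surgery
# (all patients are operated at cycle 0 and only once), so the published
# year labels are cycle labels; from the fourth cycle onward it equals the
# non-surgery value. Re-remission after relapse uses the same cycle-indexed
# value.
remission_probability <- function(ps, arm, cycle) {
  if (arm == "surgery") {
    nm <- c("p_remission_bs_y1", "p_remission_bs_y2", "p_remission_bs_y3",
            "p_remission_bs_y4plus")[min(cycle, 4)]
  } else {
    nm <- "p_remission_nonbs"
  }
  param_value(ps, nm)
}

# 1 - (1-p)(1-q): independent competing annual risks.
combine_risks <- function(p, q) 1 - (1 - p) * (1 - q)

#' Build the one-cycle transition matrix
#'
#' Assembles the 8x8 transition matrix for one (arm, cycle, age) triple.
#' From the obese-with-T2DM state: cycle-indexed remission (surgery arm
#' 0.4333/0.2941/0.0833/0.0156 for cycles 1/2/3/4+, non-surgery 0.0156),
#' annual complication risks (MI, stroke, CHF, CKD), background mortality,
#' the residual mass staying. From remission: arm-specific relapse, the
#' remission-specific complication risks, background mortality. Complication
#' states are absorbing apart from death, which combines background
#' mortality with the state-specific annual case fatality multiplicatively
#' (`1 - (1-p)(1-q)`); the first-year MI tunnel empties into the post-year
#' MI state. Rows whose outflow would exceed the mass available after death
#' raise a misspecification error; nothing is ever renormalized silently.
#'
#' @param arm `"surgery"` or `"nonsurgery"`.
#' @param cycle Cycle index (>= 1); transitions occur between cycle-1 and
#'   cycle.
#' @param age Age at the start of the cycle, used for background mortality.
#' @param params A `param_set`.
#' @param lt A `life_table` (its attached rate ratio is used unless the run
#'   configuration overrides it).
#' @return An 8x8 row-stochastic matrix over [health_states()].
#' @export
build_matrix <- function(arm, cycle, age, params, lt) {
  arm <- match.arg(arm, c("surgery", "nonsurgery"))
  stopifnot(cycle >= 1)
  d <- background_mortality(lt, age, rr = params$config$rr_mortality)
  M <- matrix(0, 8, 8, dimnames = list(HEALTH_STATES, HEALTH_STATES))

  fill_row <- function(state, to, probs, death) {
    out <- sum(probs) + death
    if (sum(probs) > 1 - death + 1e-12) {
      stop(sprintf(paste0("model misspecification in state %s (arm %s, ",
                          "cycle %d, age %s): non-death outflow %.4f exceeds ",
                          "1 - death probability %.4f"),
                   state, arm, cycle, age, sum(probs), 1 - death))
    }
    M[state, to] <<- probs
    M[state, "DEAD"] <<- death
    M[state, state] <<- M[state, state] + (1 - out)
  }

  fill_row("OBESE_T2DM",
           c("REMISSION", "MI_FIRST_YEAR", "STROKE", "CHF", "CKD"),
           c(remission_probability(params, arm, cycle),
             param_value(params, c("p_t2dm_mi", "p_t2dm_stroke",
                                   "p_t2dm_chf", "p_t2dm_ckd"))),
           d)
  fill_row("REMISSION",
           c("OBESE_T2DM", "MI_FIRST_YEAR", "STROKE", "CHF", "CKD"),
           c(param_value(params, if (arm == "surgery") "p_relapse_bs"
                         else "p_relapse_nonbs"),
             param_value(params, c("p_remission_mi", "p_remission_stroke",
                                   "p_remission_chf", "p_remission_ckd"))),
           d)
  d_mi <- combine_risks(d, param_value(params, "p_death_mi"))
  fill_row("MI_FIRST_YEAR", "MI_POST", 1 - d_mi, d_mi)
  M["MI_FIRST_YEAR", "MI_FIRST_YEAR"] <- 0  # tunnel: one cycle at most
  fill_row("MI_POST", character(0), numeric(0), d_mi)
  fill_row("STROKE", character(0), numeric(0),
           combine_risks(d, param_value(params, "p_death_stroke")))
  fill_row("CHF", character(0), numeric(0),
           combine_risks(d, param_value(params, "p_death_chf")))
  fill_row("CKD", character(0), numeric(0),
           combine_risks(d, param_value(params, "p_death_ckd")))
  M["DEAD", "DEAD"] <- 1

  if (any(M < -1e-12) || any(M > 1 + 1e-12)) {
    stop("transition probabilities outside [0, 1]")
  }
  if (any(abs(rowSums(M) - 1) > 1e-9)) stop("transition rows must sum to 1")
  M
}

#' Propagate a closed cohort through the model
#'
#' Starts the whole cohort in the obese-with-T2DM state at the configured
#' entry age and applies the cycle-indexed transition matrix until the
#' horizon cap (`max_age`) or until the living mass falls below the
#' configured occupancy floor.
#'
#' @param arm `"surgery"` or `"nonsurgery"`.
#' @param params A `param_set`.
#' @param lt A `life_table`.
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   (cycles+1 x 8 matrix of state fractions, cycle 0 first), `ages`
#'   (age at each cycle), and `arm`.
#' @export
run_cohort <- function(arm, params, lt) {
  arm <- match.arg(arm, c("surgery", "nonsurgery"))
  cfg <- params$config
  n_max <- cfg$max_age - cfg$start_age
  occ <- matrix(0, n_max + 1, 8,
                dimnames = list(0:n_max, HEALTH_STATES))
  occ[1, "OBESE_T2DM"] <- 1
  last <- 0
  for (t in seq_len(n_max)) {
    if (sum(occ[t, LIVING_STATES]) < cfg$occupancy_floor) break
    M <- build_matrix(arm, t, cfg$start_age + t - 1, params, lt)
    occ[t + 1, ] <- occ[t, ] %*% M
    last <- t
  }
  occ <- occ[seq_len(last + 1), , drop = FALSE]
  structure(list(occupancy = occ,
                 ages = cfg$start_age + 0:last,
                 arm = arm),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1
  cat(sprintf("<cohort_trace> arm %s, %d cycles (ages %d-%d), final dead %.4f\n",
              x$arm, n, x$ages[1], x$ages[n + 1],
              x$occupancy[n + 1, "DEAD"]))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = seq_len(nrow(x$occupancy)) - 1, age = x$ages,
             arm = x$arm, x$occupancy, row.names = NULL)
}

#' Undiscounted expected years per state
#'
#' Sums state occupancy over cycles 1..T (cycle 0 is the pre-transition
#' starting point and accrues nothing); the total across living states is
#' the cohort's undiscounted life expectancy over the modelled horizon.
#'
#' @param trace A `cohort_trace`.
#' @return Named numeric vector of expected years per state, with attribute
#'   `life_years`.
#' @export
state_occupancy_summary <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  occ <- trace$occupancy[-1, , drop = FALSE]
  years <- colSums(occ)
  attr(years, "life_years") <- sum(years[LIVING_STATES])
  years
}
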