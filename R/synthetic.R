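# Synthetic data: patient-level cohort histories with the transition
# structure the model assumes, interview-style cost/utility samples, a
# Gompertz background life table, and the study-design sample-size formula.
# These stand in for the hospital cohort and patient interviews, which are
# not redistributable, so every pipeline stage is testable end to end.

#' Simulate a patient-level cohort
#'
#' Draws yearly transitions for each patient with the same annual
#' probabilities the cohort engine uses (cycle-indexed remission in the
#' surgery arm, arm-specific relapse, complication risks, complication case
#' fatality, and background mortality when a life table is supplied).
#' Follow-up emulates a fixed study window: entry offsets are uniform over
#' `0..follow_up_years-1`, so observation lengths are censored uniformly
#' between one year and the full window. Default sizes mirror the source
#' cohort (30 surgical, 2,109 non-surgical patients).
#'
#' @param params A `param_set`.
#' @param lt Optional `life_table` for background mortality; `NULL` disables
#'   background deaths.
#' @param n_surgery,n_nonsurgery Patients per arm.
#' @param seed RNG seed; the simulation is deterministic given it.
#' @param follow_up_years Study window length in years.
#' @return Data frame, one row per observed patient-year: `id`, `arm`,
#'   `year` (1-based year since entry), `age`, `state` (state occupied at
#'   the start of the year), `next_state`, `event` (one of `remission`,
#'   `relapse`, `mi`, `stroke`, `chf`, `ckd`, `death`, `none`).
#' @export
generate_cohort <- function(params, lt = NULL, n_surgery = 30,
                            n_nonsurgery = 2109, seed = 1,
                            follow_up_years = 10) {
  stopifnot(n_surgery >= 0, n_nonsurgery >= 0, follow_up_years >= 1)
  if (is.null(lt)) {
    lt <- life_table(data.frame(age = 0:120, q = 0), rr = 1)
    params$config$rr_mortality <- 1
  }
  set.seed(seed)
  arms <- rep(c("surgery", "nonsurgery"), c(n_surgery, n_nonsurgery))
  n <- length(arms)
  observed <- follow_up_years - sample.int(follow_up_years, n, replace = TRUE) + 1
  start_age <- params$config$start_age
  # per-arm transition matrices; only cycles 1..4 differ (surgery remission)
  mats <- lapply(c(surgery = "surgery", nonsurgery = "nonsurgery"),
                 function(a) {
    lapply(seq_len(follow_up_years), function(t) {
      build_matrix(a, t, start_age + t - 1, params, lt)
    })
  })
  event_of <- function(from, to) {
    if (to == "DEAD") return("death")
    if (from == "OBESE_T2DM" && to == "REMISSION") return("remission")
    if (from == "REMISSION" && to == "OBESE_T2DM") return("relapse")
    if (from %in% c("OBESE_T2DM", "REMISSION")) {
      return(switch(to, MI_FIRST_YEAR = "mi", STROKE = "stroke",
                    CHF = "chf", CKD = "ckd", "none"))
    }
    "none"  # persisting in, or leaving, a complication state is not an event
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    state <- "OBESE_T2DM"
    yrs <- integer(0); sts <- character(0); nxt <- character(0)
    evs <- character(0)
    for (y in seq_len(observed[i])) {
      p <- mats[[arms[i]]][[y]][state, ]
      new_state <- sample(HEALTH_STATES, 1, prob = p)
      yrs <- c(yrs, y); sts <- c(sts, state); nxt <- c(nxt, new_state)
      evs <- c(evs, event_of(state, new_state))
      if (new_state == "DEAD") break
      state <- new_state
    }
    rows[[i]] <- data.frame(id = i, arm = arms[i], year = yrs,
                            age = start_age + yrs - 1, state = sts,
                            next_state = nxt, event = evs)
  }
  do.call(rbind, rows)
}

#' Estimate annual transition probabilities from a cohort
#'
#' Person-year event-rate estimator: events divided by person-years at risk
#' in the source state, with a binomial standard error. Surgery-arm
#' remission is stratified by year since baseline (years 1, 2, 3, 4+),
#' matching the cycle indexing of the model; relapse is estimated per arm
#' and complication risks per source state pooled over arms. Transitions
#' with no person-years at risk are returned as `NA` and flagged.
#'
#' @param cohort A patient-year data frame from [generate_cohort()].
#' @return Data frame: `parameter` (the model parameter each estimate
#'   targets), `events`, `person_years`, `estimate`, `se`.
#' @export
estimate_transition_probs <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  rate <- function(rows, ev) {
    py <- nrow(rows)
    k <- sum(rows$event %in% ev)
    est <- if (py > 0) k / py else NA_real_
    se <- if (py > 0) sqrt(max(est * (1 - est), 0) / py) else NA_real_
    c(events = k, person_years = py, estimate = est, se = se)
  }
  at_t2dm <- cohort[cohort$state == "OBESE_T2DM", ]
  at_rem <- cohort[cohort$state == "REMISSION", ]
  strata <- list(
    p_remission_bs_y1 = rate(at_t2dm[at_t2dm$arm == "surgery" &
                                       at_t2dm$year == 1, ], "remission"),
    p_remission_bs_y2 = rate(at_t2dm[at_t2dm$arm == "surgery" &
                                       at_t2dm$year == 2, ], "remission"),
    p_remission_bs_y3 = rate(at_t2dm[at_t2dm$arm == "surgery" &
                                       at_t2dm$year == 3, ], "remission"),
    p_remission_bs_y4plus = rate(at_t2dm[at_t2dm$arm == "surgery" &
                                           at_t2dm$year >= 4, ], "remission"),
    p_remission_nonbs = rate(at_t2dm[at_t2dm$arm == "nonsurgery", ],
                             "remission"),
    p_relapse_bs = rate(at_rem[at_rem$arm == "surgery", ], "relapse"),
    p_relapse_nonbs = rate(at_rem[at_rem$arm == "nonsurgery", ], "relapse"),
    p_t2dm_mi = rate(at_t2dm, "mi"),
    p_t2dm_stroke = rate(at_t2dm, "stroke"),
    p_t2dm_chf = rate(at_t2dm, "chf"),
    p_t2dm_ckd = rate(at_t2dm, "ckd"),
    p_remission_mi = rate(at_rem, "mi"),
    p_remission_stroke = rate(at_rem, "stroke"),
    p_remission_chf = rate(at_rem, "chf"),
    p_remission_ckd = rate(at_rem, "ckd")
  )
  out <- data.frame(parameter = names(strata),
                    do.call(rbind, strata), row.names = NULL)
  if (anyNA(out$estimate)) {
    warning("no person-years at risk for: ",
            paste(out$parameter[is.na(out$estimate)], collapse = ", "))
  }
  out
}

#' Cohort descriptive rates
#'
#' Per-arm count and percentage of patients ever achieving remission, and
#' the percentage with a complication among patients in the
#' non-remission-or-relapsed group (those not in remission at the end of
#' their observation).
#'
#' @param cohort A patient-year data frame from [generate_cohort()].
#' @return List: `by_arm` data frame (`arm`, `n`, `n_remission`,
#'   `remission_pct`) and `complications` (`n_at_risk`, `n_complication`,
#'   `complication_pct`).
#' @export
cohort_descriptives <- function(cohort) {
  split_id <- split(cohort, cohort$id)
  per <- do.call(rbind, lapply(split_id, function(d) {
    data.frame(arm = d$arm[1],
               remission = any(d$event == "remission"),
               complication = any(d$event %in% c("mi", "stroke", "chf",
                                                 "ckd")),
               end_remitted = d$next_state[nrow(d)] == "REMISSION")
  }))
  by_arm <- do.call(rbind, lapply(split(per, per$arm), function(g) {
    data.frame(arm = g$arm[1], n = nrow(g), n_remission = sum(g$remission),
               remission_pct = 100 * mean(g$remission))
  }))
  rownames(by_arm) <- NULL
  at_risk <- per[!per$end_remitted, ]
  list(by_arm = by_arm,
       complications = data.frame(
         n_at_risk = nrow(at_risk),
         n_complication = sum(at_risk$complication),
         complication_pct = 100 * mean(at_risk$complication)))
}

#' Draw an interview-style sample for one parameter
#'
#' Samples `n` observations from the parameter's assigned distribution
#' (costs from the gamma family, probabilities/utilities from the beta
#' family), emulating the face-to-face interview data the input table
#' summarises.
#'
#' @param spec One-row parameter spec, see [param_spec()].
#' @param n Sample size.
#' @param seed Master seed (substream keyed by parameter name).
#' @return Numeric vector of length `n`.
#' @export
generate_interview_sample <- function(spec, n, seed = 1) {
  suppressMessages(sample_parameter(spec, n, seed))
}

#' Required sample size for estimating a mean cost
#'
#' `n = ceiling(z^2 * sigma^2 / (mu^2 * epsilon^2))`: the sample size for
#' estimating a mean to within relative margin `epsilon` when the standard
#' deviation is `sigma`. With `z = 1.96`, `sigma = 0.5 * mu` and
#' `epsilon = 0.15` this gives 43 per group.
#'
#' @param z Standard-normal quantile (e.g. 1.96 for 95% confidence).
#' @param sigma Standard deviation.
#' @param mu Mean.
#' @param epsilon Relative margin of error (> 0).
#' @return Integer sample size.
#' @export
required_sample_size <- function(z, sigma, mu, epsilon) {
  stopifnot(z > 0, sigma > 0, mu > 0)
  if (epsilon <= 0) stop("epsilon must be positive")
  as.integer(ceiling(z^2 * sigma^2 / (mu^2 * epsilon^2)))
}

#' Generate a Gompertz background life table
#'
#' Annual death probability `q(age) = min(1, a * exp(b * age))` over ages
#' 0..`max_age`; monotone nondecreasing by construction. The defaults
#' (`a = 6.08e-5`, `b = 0.09`) give a life expectancy of about 75 years at
#' birth, a plausible national level; the published national life table is
#' not redistributed, so this synthetic table is the packaged fixture.
#'
#' @param a Baseline hazard level (> 0).
#' @param b Log-hazard slope per year of age (>= 0; 0 gives a constant
#'   hazard).
#' @param max_age Last tabulated age.
#' @param rr Mortality rate ratio to attach.
#' @return A `life_table`.
#' @export
generate_life_table <- function(a = 6.08e-5, b = 0.09, max_age = 100, rr = 1) {
  if (a <= 0) stop("a must be positive")
  if (b < 0) stop("b must be nonnegative")
  ages <- 0:max_age
  life_table(data.frame(age = ages, q = pmin(1, a * exp(b * ages))), rr = rr)
}
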