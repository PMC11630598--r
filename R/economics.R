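# Valuation of cohort traces: per-state annual costs (direct medical, direct
# non-medical) and utilities, discounted accumulation, and comparative
# cost-effectiveness.
#
# Perspectives: the payer perspective counts direct medical costs only; the
# societal perspective adds direct non-medical costs (no productivity losses
# are modelled). The one-time preoperative-and-surgery cost is a direct
# medical cost incurred at cycle 0 in the surgery arm, under both
# perspectives.

#' Discount factor
#'
#' @param rate Annual discount rate (>= 0).
#' @param t Cycle index (years from baseline).
#' @return `(1 + rate)^(-t)`.
#' @export
discount_factor <- function(rate, t) {
  stopifnot(rate >= 0, all(t >= 0))
  (1 + rate)^(-t)
}

#' Annual direct medical cost of a state
#'
#' Year-since-baseline indexed where the input table splits costs by year
#' (surgery-arm treatment costs, years 1/2/3+); the first-year MI tunnel
#' state carries the first-year MI treatment cost, the post-year state the
#' later-years cost.
#'
#' @param params A `param_set`.
#' @param state One of [health_states()].
#' @param arm `"surgery"` or `"nonsurgery"`.
#' @param cycle Cycle index (>= 1).
#' @return Annual cost in baht.
#' @export
annual_medical_cost <- function(params, state, arm, cycle) {
  y <- min(cycle, 3)
  switch(state,
    OBESE_T2DM = if (arm == "surgery") {
      param_value(params, c("c_treat_t2dm_bs_y1", "c_treat_t2dm_bs_y2",
                            "c_treat_t2dm_bs_y3plus")[y])
    } else param_value(params, "c_treat_t2dm_nonbs"),
    REMISSION = if (arm == "surgery") {
      param_value(params, c("c_treat_remission_bs_y1",
                            "c_treat_remission_bs_y2",
                            "c_treat_remission_bs_y3plus")[y])
    } else param_value(params, "c_treat_remission_nonbs"),
    MI_FIRST_YEAR = param_value(params, "c_mi_y1"),
    MI_POST = param_value(params, "c_mi_later"),
    STROKE = param_value(params, "c_stroke"),
    CHF = param_value(params, "c_chf"),
    CKD = param_value(params, "c_ckd"),
    DEAD = 0
  )
}

#' Annual direct non-medical cost of a state
#'
#' For the obese-with-T2DM and remission states: per-visit items (travel,
#' food, hotel, informal care at the visit) multiplied by the configured
#' outpatient/inpatient frequencies, plus annual items (informal daily care,
#' hired assistance, treatment outside the hospital -- arm-specific where
#' the input table splits it), plus first-year-only items (accommodation,
#' home renovation) at cycle 1. Complication states carry their
#' literature-derived annual totals instead.
#'
#' @param params A `param_set`.
#' @param state One of [health_states()].
#' @param arm `"surgery"` or `"nonsurgery"`.
#' @param cycle Cycle index (>= 1).
#' @param visit_profile List with outpatient visits/year for non-remission
#'   (`op_t2dm`) and remission (`op_remission`) and inpatient
#'   admissions/year (`ip`). Defaults to the run configuration's profile.
#' @return Annual cost in baht.
#' @export
annual_nonmedical_cost <- function(params, state, arm, cycle,
                                   visit_profile = params$config$visit_profile) {
  need <- setdiff(c("op_t2dm", "op_remission", "ip"), names(visit_profile))
  if (length(need) > 0) {
    stop("visit_profile missing frequencies: ", paste(need, collapse = ", "))
  }
  op_cost <- sum(param_value(params, c("c_op_travel", "c_op_food",
                                       "c_op_hotel", "c_op_informal")))
  ip_cost <- sum(param_value(params, c("c_ip_travel", "c_ip_food",
                                       "c_ip_informal")))
  first_year <- if (cycle == 1) {
    sum(param_value(params, c("c_accommodation_y1", "c_renovation_y1")))
  } else 0
  switch(state,
    OBESE_T2DM = visit_profile$op_t2dm * op_cost + visit_profile$ip * ip_cost +
      sum(param_value(params, c("c_informal_t2dm", "c_hiring_t2dm"))) +
      param_value(params, if (arm == "surgery") "c_outside_t2dm_bs"
                  else "c_outside_t2dm_nonbs") +
      first_year,
    REMISSION = visit_profile$op_remission * op_cost +
      visit_profile$ip * ip_cost +
      sum(param_value(params, c("c_informal_remission", "c_hiring_remission",
                                "c_outside_remission"))) +
      first_year,
    MI_FIRST_YEAR = param_value(params, "c_nonmed_mi"),
    MI_POST = param_value(params, "c_nonmed_mi"),
    STROKE = param_value(params, "c_nonmed_stroke"),
    CHF = param_value(params, "c_nonmed_chf"),
    CKD = param_value(params, "c_nonmed_ckd"),
    DEAD = 0
  )
}

#' Per-state value table for one arm and perspective
#'
#' Precomputes the annual cost of every state for cycles 1..`n_cycles`
#' (year-dependence only enters through the year-1/2/3+ cost splits and the
#' first-year-only items), the utility weight of every state, and the
#' one-time surgery cost.
#'
#' @param params A `param_set`.
#' @param arm `"surgery"` or `"nonsurgery"`.
#' @param perspective `"payer"` (direct medical) or `"societal"` (direct
#'   medical + direct non-medical).
#' @param n_cycles Number of cycles to tabulate.
#' @return List with `cost` (8 x `n_cycles` matrix), `utility` (length-8
#'   vector), `one_time` (surgery cost at cycle 0; 0 in the non-surgery
#'   arm).
#' @export
state_value_table <- function(params, arm, perspective = c("payer", "societal"),
                              n_cycles) {
  arm <- match.arg(arm, c("surgery", "nonsurgery"))
  perspective <- match.arg(perspective)
  cost <- matrix(0, 8, n_cycles, dimnames = list(HEALTH_STATES, NULL))
  # cycles beyond 3 reuse the cycle-3 ("3rd year and onward") column except
  # that the first-year-only non-medical items never recur
  for (t in seq_len(min(n_cycles, 3))) {
    for (s in HEALTH_STATES) {
      v <- annual_medical_cost(params, s, arm, t)
      if (perspective == "societal") {
        v <- v + annual_nonmedical_cost(params, s, arm, t)
      }
      cost[s, t] <- v
    }
  }
  if (n_cycles > 3) cost[, 4:n_cycles] <- cost[, 3]
  utility <- c(OBESE_T2DM = param_value(params, "u_t2dm"),
               REMISSION = param_value(params, "u_remission"),
               MI_FIRST_YEAR = param_value(params, "u_mi"),
               MI_POST = param_value(params, "u_mi"),
               STROKE = param_value(params, "u_stroke"),
               CHF = param_value(params, "u_chf"),
               CKD = param_value(params, "u_ckd"),
               DEAD = 0)
  list(cost = cost, utility = utility,
       one_time = if (arm == "surgery") param_value(params, "c_surgery") else 0)
}

#' Accumulate discounted cost, life years and QALYs over a trace
#'
#' State values accrue at cycles 1..T using the end-of-cycle occupancy,
#' discounted by `(1+rate)^-t`; the one-time surgery cost sits at cycle 0
#' undiscounted. With the half-cycle correction enabled, each year's
#' occupancy is the average of the occupancies at its two bounding cycles.
#'
#' @param trace A `cohort_trace`.
#' @param values A value table from [state_value_table()] covering at least
#'   as many cycles as the trace.
#' @param rate Annual discount rate.
#' @param half_cycle Apply the half-cycle correction?
#' @return List with `cost`, `ly`, `qaly`.
#' @export
accumulate_outcomes <- function(trace, values, rate, half_cycle = FALSE) {
  occ <- trace$occupancy
  n <- nrow(occ) - 1
  stopifnot(ncol(values$cost) >= n)
  w <- if (half_cycle) (occ[1:n, , drop = FALSE] +
                        occ[2:(n + 1), , drop = FALSE]) / 2
       else occ[2:(n + 1), , drop = FALSE]
  df <- discount_factor(rate, seq_len(n))
  living <- as.numeric(colnames(occ) %in% LIVING_STATES)
  list(cost = values$one_time +
         sum(df * rowSums(w * t(values$cost[, seq_len(n), drop = FALSE]))),
       ly = sum(df * (w %*% living)),
       qaly = sum(df * (w %*% values$utility)))
}

#' Discounted lifetime outcomes for one arm
#'
#' Runs the cohort once and values it under both perspectives.
#'
#' @param arm `"surgery"` or `"nonsurgery"`.
#' @param params A `param_set`.
#' @param lt A `life_table`.
#' @return An `econ_outcome`: list with `arm`, `cost_payer`,
#'   `cost_societal`, `ly`, `qaly`, and the trace.
#' @export
evaluate_arm <- function(arm, params, lt) {
  trace <- run_cohort(arm, params, lt)
  n <- nrow(trace$occupancy) - 1
  cfg <- params$config
  payer <- accumulate_outcomes(trace,
                               state_value_table(params, arm, "payer", n),
                               cfg$discount_rate, cfg$half_cycle)
  societal <- accumulate_outcomes(trace,
                                  state_value_table(params, arm, "societal", n),
                                  cfg$discount_rate, cfg$half_cycle)
  structure(list(arm = arm, cost_payer = payer$cost,
                 cost_societal = societal$cost,
                 ly = payer$ly, qaly = payer$qaly, trace = trace),
            class = "econ_outcome")
}

#' Compare two strategies
#'
#' Computes incremental cost, QALYs and life years, the ICER, the dominance
#' verdict, and the cost-effectiveness flag at the willingness-to-pay
#' threshold (an ICER exactly at the threshold counts as cost-effective).
#'
#' @param intervention,comparator `econ_outcome` objects from the same
#'   perspective family (the perspective chooses which cost field is used).
#' @param threshold Willingness-to-pay, baht per QALY.
#' @param perspective `"payer"` or `"societal"`.
#' @return A `cea_result`: list with the incremental quantities, `icer_qaly`
#'   and `icer_ly` (NA when the denominator is zero), `verdict` in
#'   `{dominant, dominated, ICER}`, and `cost_effective`.
#' @export
compare_strategies <- function(intervention, comparator, threshold,
                               perspective = c("payer", "societal")) {
  perspective <- match.arg(perspective)
  field <- if (perspective == "payer") "cost_payer" else "cost_societal"
  d_cost <- intervention[[field]] - comparator[[field]]
  d_qaly <- intervention$qaly - comparator$qaly
  d_ly <- intervention$ly - comparator$ly
  icer <- if (d_qaly != 0) d_cost / d_qaly else NA_real_
  icer_ly <- if (d_ly != 0) d_cost / d_ly else NA_real_
  verdict <- if (d_cost <= 0 && d_qaly >= 0 && !(d_cost == 0 && d_qaly == 0)) {
    "dominant"
  } else if (d_cost >= 0 && d_qaly <= 0 && !(d_cost == 0 && d_qaly == 0)) {
    "dominated"
  } else "ICER"
  cost_effective <- verdict == "dominant" ||
    (verdict == "ICER" && d_qaly > 0 && icer <= threshold) ||
    (verdict == "ICER" && d_qaly < 0 && icer >= threshold)
  structure(list(perspective = perspective, d_cost = d_cost, d_qaly = d_qaly,
                 d_ly = d_ly, icer_qaly = icer, icer_ly = icer_ly,
                 verdict = verdict, threshold = threshold,
                 cost_effective = cost_effective,
                 intervention = intervention, comparator = comparator),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s perspective: dCost %.2f, dQALY %.4f",
              x$perspective, x$d_cost, x$d_qaly))
  if (x$verdict == "ICER") {
    cat(sprintf(", ICER %.2f baht/QALY", x$icer_qaly))
  } else cat(sprintf(", %s", x$verdict))
  cat(sprintf(" (%scost-effective at %s)\n",
              if (x$cost_effective) "" else "not ",
              format(x$threshold, big.mark = ",")))
  invisible(x)
}

#' Full base-case cost-utility analysis
#'
#' Runs both arms and compares them under both perspectives.
#'
#' @param params A `param_set`.
#' @param lt A `life_table`.
#' @return List with the two `econ_outcome`s (`surgery`, `nonsurgery`), the
#'   two `cea_result`s (`payer`, `societal`), and `table`, a data frame in
#'   published-results layout (one row per arm and perspective with lifetime
#'   cost, LY, QALY and ICERs).
#' @export
run_cea <- function(params, lt) {
  surgery <- evaluate_arm("surgery", params, lt)
  nonsurgery <- evaluate_arm("nonsurgery", params, lt)
  thr <- params$config$wtp_threshold
  payer <- compare_strategies(surgery, nonsurgery, thr, "payer")
  societal <- compare_strategies(surgery, nonsurgery, thr, "societal")
  tab <- data.frame(
    perspective = rep(c("payer", "societal"), each = 2),
    strategy = rep(c("bariatric surgery", "non-surgery"), 2),
    cost = c(surgery$cost_payer, nonsurgery$cost_payer,
             surgery$cost_societal, nonsurgery$cost_societal),
    ly = rep(c(surgery$ly, nonsurgery$ly), 2),
    qaly = rep(c(surgery$qaly, nonsurgery$qaly), 2),
    icer_ly = c(payer$icer_ly, NA, societal$icer_ly, NA),
    icer_qaly = c(payer$icer_qaly, NA, societal$icer_qaly, NA)
  )
  list(surgery = surgery, nonsurgery = nonsurgery,
       payer = payer, societal = societal, table = tab)
}
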