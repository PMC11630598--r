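# Budget impact analysis: the national eligible-population cascade and the
# undiscounted 5-year budget projection for funding bariatric surgery.

#' Default budget impact configuration
#'
#' National population inputs for the eligible-population cascade: the
#' 18-65 population, the BMI>=30 population, obesity-class shares used for
#' within-class interpolation of the BMI cut, the T2DM share among obesity,
#' 8-year cumulative T2DM incidences by sex, and the published headline
#' counts carried as constants (the cascade also reports the values
#' re-derived from the rates, which differ slightly because of stratum-level
#' rounding upstream). Uptake defaults to 100% of the prevalent stock
#' operated in the first year, with incident cohorts treated in their entry
#' year.
#'
#' @return Named list of BIA settings.
#' @export
default_bia_config <- function() {
  yaml::read_yaml(system.file("extdata", "bia_config.yaml",
                              package = "bariaCEA"))
}

#' Load a BIA configuration from YAML
#'
#' Merged over [default_bia_config()].
#'
#' @param path Path to a YAML file.
#' @return Named list of BIA settings.
#' @export
load_bia_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- utils::modifyList(default_bia_config(), yaml::read_yaml(path))
  validate_bia_config(cfg)
  cfg
}

validate_bia_config <- function(cfg) {
  fr <- c(cfg$t2dm_share, cfg$incidence_8yr_men, cfg$incidence_8yr_women,
          cfg$male_share_at_risk)
  if (any(fr < 0 | fr > 1)) stop("BIA fractions must lie in [0, 1]")
  if (cfg$horizon_years < 1) stop("horizon_years must be >= 1")
  if (any(cfg$uptake < 0 | cfg$uptake > 1)) stop("uptake must lie in [0, 1]")
  if (sum(cfg$uptake) > 1) {
    stop("uptake schedule sums above 1 over the horizon")
  }
  if (any(unlist(cfg$class_shares_pct) < 0)) stop("class shares must be >= 0")
  invisible(cfg)
}

#' Share of the BMI>=30 population above a BMI cut
#'
#' Obesity-class shares are given for class I (30-34.9), class II (35-39.9)
#' and class III (>=40). The share above `cut` interpolates linearly within
#' the class band containing the cut and counts higher bands fully; e.g.
#' shares 4.0/0.8/0.1 with cut 32.5 give (0.5*4.0 + 0.8 + 0.1)/4.9 = 59.2%.
#'
#' @param class_shares Length-3 vector of class I/II/III shares (any common
#'   unit; only ratios matter).
#' @param cut BMI threshold in `[30, 40]`.
#' @return Fraction (0-1) of the BMI>=30 population with BMI >= `cut`.
#' @export
class_share_above_cut <- function(class_shares, cut) {
  stopifnot(length(class_shares) == 3, all(class_shares >= 0))
  if (cut < 30) stop("cut must be at least 30")
  if (cut > 40) stop("cut must be at most 40")
  f1 <- min(1, max(0, (35 - cut) / 5))
  f2 <- min(1, max(0, (40 - cut) / 5))
  sum(class_shares * c(f1, f2, 1)) / sum(class_shares)
}

#' Convert a multi-year cumulative incidence to an annual probability
#'
#' `1 - (1 - p)^(1/years)`: the constant annual probability that compounds
#' to the given cumulative incidence.
#'
#' @param p_multi Cumulative incidence over `years` (in `[0, 1)`).
#' @param years Number of years (>= 1).
#' @return Annual probability.
#' @export
annualize_incidence <- function(p_multi, years) {
  stopifnot(p_multi >= 0, p_multi < 1, years >= 1)
  1 - (1 - p_multi)^(1 / years)
}

#' Eligible-population cascade
#'
#' Emits every stage of the filter chain from the national 18-65 population
#' down to the annual incident cases: total, BMI>=30, BMI above the cut,
#' with T2DM, at risk without T2DM, and annual incident T2DM cases. Each
#' stage carries the count used downstream (the published constant where
#' one exists) alongside the value re-derived from the configured rates.
#'
#' @param config BIA configuration, see [default_bia_config()].
#' @return Data frame with `stage`, `count` (value used), `derived`
#'   (recomputed from rates; NA where the stage is a direct input).
#' @export
eligible_population <- function(config = default_bia_config()) {
  validate_bia_config(config)
  share <- class_share_above_cut(unlist(config$class_shares_pct),
                                 config$bmi_cut)
  derived_cut <- config$bmi30_population * share
  used_cut <- config$bmi_eligible_population %||% derived_cut
  derived_t2dm <- used_cut * config$t2dm_share
  used_t2dm <- config$eligible_t2dm_population %||% derived_t2dm
  derived_risk <- used_cut - used_t2dm
  used_risk <- config$at_risk_population %||% derived_risk
  p_ann <- config$male_share_at_risk *
    annualize_incidence(config$incidence_8yr_men, 8) +
    (1 - config$male_share_at_risk) *
    annualize_incidence(config$incidence_8yr_women, 8)
  derived_inc <- used_risk * p_ann
  used_inc <- config$annual_incident_cases %||% derived_inc
  out <- data.frame(
    stage = c("population_18_65", "bmi_ge_30", "bmi_ge_cut", "with_t2dm",
              "at_risk_no_t2dm", "annual_incident_t2dm"),
    count = c(config$total_population_18_65, config$bmi30_population,
              used_cut, used_t2dm, used_risk, used_inc),
    derived = c(NA, NA, derived_cut, derived_t2dm, derived_risk, derived_inc)
  )
  # filter chain total -> bmi30 -> cut -> t2dm must be decreasing; the
  # at-risk branch is the complement of the T2DM split within the cut stage
  if (any(diff(out$count[1:4]) > 0) || used_risk > used_cut ||
      used_inc > used_risk) {
    stop("inconsistent BIA configuration: cascade counts must be decreasing")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected annual per-patient payer cost by year since baseline
#'
#' Undiscounted expected direct medical cost per enrolled patient for each
#' of the first `years` years, from the Markov trace (so remission mix,
#' complications and deaths are reflected); the one-time surgery cost is
#' added to year 1 in the surgery arm.
#'
#' @param arm `"surgery"` or `"nonsurgery"`.
#' @param params A `param_set`.
#' @param lt A `life_table`.
#' @param years Number of years to report.
#' @return Numeric vector of length `years`, baht per enrollee.
#' @export
annual_cost_profile <- function(arm, params, lt, years = 5) {
  trace <- run_cohort(arm, params, lt)
  n <- min(years, nrow(trace$occupancy) - 1)
  values <- state_value_table(params, arm, "payer", n)
  occ <- trace$occupancy[2:(n + 1), , drop = FALSE]
  prof <- rowSums(occ * t(values$cost[, seq_len(n), drop = FALSE]))
  prof[1] <- prof[1] + values$one_time
  unname(prof)
}

#' Five-year budget projection
#'
#' Projects the annual national budget under the surgery scenario against
#' the no-surgery comparator, undiscounted (the usual budget-impact
#' convention). Cohorts: the prevalent eligible stock is operated according
#' to the uptake schedule; incident cohorts (constant per year) are operated
#' in their entry year. Every cohort then accrues the per-patient annual
#' payer cost profile of its arm by year since entry; untreated patients
#' accrue the non-surgery profile in both scenarios, so the incremental
#' budget is driven by the treated.
#'
#' @param config BIA configuration.
#' @param params A `param_set`.
#' @param lt A `life_table`.
#' @return A `bia_result`: list with `by_year` (data frame: year index,
#'   treated count, scenario/comparator/incremental budgets in baht) and
#'   `totals` (5-year sums, plus `incremental_million`).
#' @export
project_budget <- function(config = default_bia_config(), params, lt) {
  validate_bia_config(config)
  casc <- eligible_population(config)
  prevalent <- casc$count[casc$stage == "with_t2dm"]
  incident <- casc$count[casc$stage == "annual_incident_t2dm"]
  h <- config$horizon_years
  uptake <- rep_len(c(config$uptake, rep(0, h)), h)
  prof_s <- annual_cost_profile("surgery", params, lt, h)
  prof_n <- annual_cost_profile("nonsurgery", params, lt, h)
  # treated cohort entering each year: share of the prevalent stock plus the
  # full incident cohort from year 2 on
  treated_new <- uptake * prevalent + c(0, rep(incident, h - 1))
  eligible_new <- c(prevalent, rep(incident, h - 1))
  untreated_new <- eligible_new - treated_new
  scenario <- comparator <- treated <- numeric(h)
  for (y in seq_len(h)) {
    k <- y - seq_len(y) + 1  # years since entry for cohorts entering 1..y
    scenario[y] <- sum(treated_new[seq_len(y)] * prof_s[k] +
                       untreated_new[seq_len(y)] * prof_n[k])
    comparator[y] <- sum(eligible_new[seq_len(y)] * prof_n[k])
    treated[y] <- treated_new[y]
  }
  by_year <- data.frame(year = seq_len(h),
                        eligible_new = eligible_new,
                        treated_new = treated,
                        budget_scenario = scenario,
                        budget_comparator = comparator,
                        incremental = scenario - comparator)
  totals <- list(scenario = sum(scenario), comparator = sum(comparator),
                 incremental = sum(scenario) - sum(comparator),
                 incremental_million = (sum(scenario) - sum(comparator)) / 1e6,
                 treated = sum(treated))
  structure(list(by_year = by_year, totals = totals, cascade = casc),
            class = "bia_result")
}

#' @export
print.bia_result <- function(x, ...) {
  cat(sprintf(paste0("<bia_result> %d-year horizon: %.0f treated, ",
                     "incremental budget %.0f million baht\n"),
              nrow(x$by_year), x$totals$treated, x$totals$incremental_million))
  invisible(x)
}

#' Surgery share of first-year scenario cost per patient
#'
#' For one operated patient, the preoperative-and-surgery cost as a
#' fraction of surgery plus first-year treatment cost.
#'
#' @param params A `param_set`.
#' @return Fraction in (0, 1).
#' @export
first_year_surgery_share <- function(params) {
  cs <- param_value(params, "c_surgery")
  cs / (cs + param_value(params, "c_treat_t2dm_bs_y1"))
}
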