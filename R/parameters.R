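# Parameter management: the in-memory input table (distribution family,
# mean, SE per parameter), run configuration, and validation.

# Every parameter name the engine and the valuation code reference.
REQUIRED_PARAMS <- c(
  "p_remission_nonbs", "p_remission_bs_y1", "p_remission_bs_y2",
  "p_remission_bs_y3", "p_remission_bs_y4plus", "p_relapse_nonbs",
  "p_relapse_bs", "p_t2dm_mi", "p_t2dm_stroke", "p_t2dm_chf", "p_t2dm_ckd",
  "p_remission_mi", "p_remission_stroke", "p_remission_chf", "p_remission_ckd",
  "p_death_mi", "p_death_stroke", "p_death_chf", "p_death_ckd",
  "c_treat_t2dm_nonbs", "c_treat_remission_nonbs", "c_surgery",
  "c_treat_t2dm_bs_y1", "c_treat_t2dm_bs_y2", "c_treat_t2dm_bs_y3plus",
  "c_treat_remission_bs_y1", "c_treat_remission_bs_y2",
  "c_treat_remission_bs_y3plus", "c_mi_y1", "c_mi_later", "c_stroke",
  "c_chf", "c_ckd",
  "c_accommodation_y1", "c_renovation_y1", "c_op_travel", "c_op_food",
  "c_op_hotel", "c_op_informal", "c_ip_travel", "c_ip_food", "c_ip_informal",
  "c_informal_t2dm", "c_hiring_t2dm", "c_informal_remission",
  "c_hiring_remission", "c_outside_remission", "c_outside_t2dm_nonbs",
  "c_outside_t2dm_bs", "c_nonmed_mi", "c_nonmed_stroke", "c_nonmed_chf",
  "c_nonmed_ckd",
  "u_t2dm", "u_remission", "u_mi", "u_stroke", "u_chf", "u_ckd"
)

#' Default run configuration
#'
#' Settings of the lifetime cost-utility model: 3% annual discounting of
#' costs and outcomes, a willingness-to-pay threshold of 160,000 baht/QALY,
#' cohort entry at age 40 with a one-year cycle and a horizon capped at age
#' 100, and a mortality rate ratio of 2.0 applied to the background life
#' table (a documented placeholder; the published source value is not
#' available, so results are examined over an RR grid rather than pinned to
#' it). `visit_profile` supplies the outpatient/inpatient frequencies used to
#' annualize per-visit non-medical cost items; these are modelling
#' assumptions, not published quantities.
#'
#' @return A named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    discount_rate = 0.03,
    wtp_threshold = 160000,
    start_age = 40,
    max_age = 100,
    cycle_length = 1,
    rr_mortality = 2.0,
    half_cycle = FALSE,
    occupancy_floor = 1e-5,
    psa_draws = 1000,
    seed = 4243,
    visit_profile = list(op_t2dm = 4, op_remission = 2, ip = 0.1)
  )
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file and merges it over [default_run_config()]; keys absent
#' from the file keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A configuration list.
#' @export
load_run_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- utils::modifyList(default_run_config(), yaml::read_yaml(path))
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$discount_rate < 0) stop("discount_rate must be >= 0")
  if (cfg$cycle_length != 1) stop("only a one-year cycle length is supported")
  if (cfg$start_age >= cfg$max_age) stop("start_age must be below max_age")
  if (cfg$rr_mortality <= 0) stop("rr_mortality must be positive")
  vp <- cfg$visit_profile
  if (!all(c("op_t2dm", "op_remission", "ip") %in% names(vp))) {
    stop("visit_profile must supply op_t2dm, op_remission and ip frequencies")
  }
  invisible(cfg)
}

#' Load and validate the model parameter table
#'
#' Reads a comma-delimited parameter table (columns `name`, `family`, `mean`,
#' `se`, `role`, `arm_scope`, `cycle_scope`; `#` comment lines allowed) and
#' returns a validated parameter set. Every parameter the model references
#' must be present exactly once; beta-distributed entries must satisfy the
#' moment feasibility condition `se^2 < mean * (1 - mean)`.
#'
#' @param path Path to the parameter CSV. Defaults to the packaged
#'   transcription of the published input table.
#' @param config Run configuration list, see [default_run_config()].
#' @return An object of class `param_set`: list with elements `specs` (the
#'   validated parameter data frame) and `config`.
#' @export
load_parameters <- function(path = system.file("extdata", "parameters.csv",
                                               package = "bariaCEA"),
                            config = default_run_config()) {
  stopifnot(file.exists(path))
  specs <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                           colClasses = c(cycle_scope = "character"))
  needed_cols <- c("name", "family", "mean", "se", "role", "arm_scope",
                   "cycle_scope")
  missing_cols <- setdiff(needed_cols, names(specs))
  if (length(missing_cols) > 0) {
    stop("parameter table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- specs$name[duplicated(specs$name)]
  if (length(dup) > 0) {
    stop("duplicate parameter names: ", paste(unique(dup), collapse = ", "))
  }
  absent <- setdiff(REQUIRED_PARAMS, specs$name)
  if (length(absent) > 0) {
    stop("parameter table is missing required parameters: ",
         paste(absent, collapse = ", "))
  }
  validate_run_config(config)
  ps <- structure(list(specs = specs, config = config), class = "param_set")
  validate_parameters(ps)
  ps
}

validate_parameters <- function(ps) {
  specs <- ps$specs
  bad_family <- setdiff(unique(specs$family), c("beta", "gamma", "fixed"))
  if (length(bad_family) > 0) {
    stop("unknown distribution family: ", paste(bad_family, collapse = ", "))
  }
  if (any(specs$se < 0)) {
    stop("negative SE for: ",
         paste(specs$name[specs$se < 0], collapse = ", "))
  }
  b <- specs[specs$family == "beta", ]
  out_of_range <- b$name[b$mean < 0 | b$mean > 1]
  if (length(out_of_range) > 0) {
    stop("beta parameter mean outside [0, 1]: ",
         paste(out_of_range, collapse = ", "))
  }
  infeasible <- b$name[b$se > 0 & b$se^2 >= b$mean * (1 - b$mean)]
  if (length(infeasible) > 0) {
    stop("beta variance infeasible (se^2 >= mean*(1-mean)) for: ",
         paste(infeasible, collapse = ", "))
  }
  g <- specs[specs$family == "gamma", ]
  nonpos <- g$name[g$mean <= 0]
  if (length(nonpos) > 0) {
    stop("gamma parameter mean must be positive: ",
         paste(nonpos, collapse = ", "))
  }
  invisible(ps)
}

#' @export
print.param_set <- function(x, ...) {
  cat(sprintf("<param_set> %d parameters (%s)\n", nrow(x$specs),
              paste(sprintf("%s: %d", names(table(x$specs$role)),
                            as.integer(table(x$specs$role))),
                    collapse = ", ")))
  cat(sprintf("  discount %.1f%%/yr, WTP %s baht/QALY, ages %d-%d, RR %.2f\n",
              100 * x$config$discount_rate,
              format(x$config$wtp_threshold, big.mark = ","),
              x$config$start_age, x$config$max_age, x$config$rr_mortality))
  invisible(x)
}

#' Look up a parameter value
#'
#' @param ps A `param_set`.
#' @param name Parameter name(s).
#' @return The mean value(s) currently stored for `name`.
#' @export
param_value <- function(ps, name) {
  idx <- match(name, ps$specs$name)
  if (anyNA(idx)) {
    stop("unknown parameter(s): ", paste(name[is.na(idx)], collapse = ", "))
  }
  ps$specs$mean[idx]
}

#' Return the spec row for a parameter
#' @inheritParams param_value
#' @return A one-row data frame.
#' @export
param_spec <- function(ps, name) {
  idx <- match(name, ps$specs$name)
  if (anyNA(idx)) stop("unknown parameter(s): ",
                       paste(name[is.na(idx)], collapse = ", "))
  ps$specs[idx, , drop = FALSE]
}

#' Replace parameter values
#'
#' Returns a copy of the parameter set with the means of the named
#' parameters replaced, e.g. by one Monte Carlo draw or a one-way
#' sensitivity bound. Distribution families and SEs are untouched.
#'
#' @param ps A `param_set`.
#' @param values Named numeric vector of replacement values.
#' @return The modified `param_set`.
#' @export
set_param_values <- function(ps, values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  idx <- match(names(values), ps$specs$name)
  if (anyNA(idx)) {
    stop("unknown parameter(s): ",
         paste(names(values)[is.na(idx)], collapse = ", "))
  }
  ps$specs$mean[idx] <- unname(values)
  ps
}
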