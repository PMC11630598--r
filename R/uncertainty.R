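# Uncertainty analysis: one-way (tornado) deterministic sensitivity and
# probabilistic sensitivity analysis (PSA) with the cost-effectiveness
# acceptability curve.

#' One-way sensitivity of the ICER to a single parameter
#'
#' Re-runs both arms deterministically with the named parameter set to its
#' low and high bound (all other parameters at their base means) and records
#' the ICER at each. Bounds default to the central 95% interval of the
#' parameter's assigned distribution; the published analysis does not state
#' its ranges, so this is the package's documented convention. User-supplied
#' bounds outside the parameter's domain are clipped with a warning. The
#' ICER is reported as the raw incremental-cost / incremental-QALY quotient,
#' so dominance at a bound shows up as a negative value.
#'
#' @param params A `param_set`.
#' @param lt A `life_table`.
#' @param name Parameter name.
#' @param bounds Optional numeric `c(low, high)` overriding the default.
#' @param perspective `"payer"` or `"societal"`.
#' @param level Interval coverage for the default bounds.
#' @return One-row data frame: `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `range` (absolute ICER spread).
#' @export
one_way <- function(params, lt, name, bounds = NULL,
                    perspective = c("societal", "payer"), level = 0.95) {
  perspective <- match.arg(perspective)
  spec <- param_spec(params, name)
  if (is.null(bounds)) {
    bounds <- parameter_interval(spec, level)
  } else {
    stopifnot(length(bounds) == 2, bounds[1] <= bounds[2])
    dom <- if (spec$family == "beta") c(0, 1) else c(0, Inf)
    if (any(bounds < dom[1]) || any(bounds > dom[2])) {
      warning("bounds for '", name, "' clipped to the parameter domain")
      bounds <- pmin(pmax(bounds, dom[1]), dom[2])
    }
  }
  icer_at <- function(v) {
    res <- run_cea(set_param_values(params, stats::setNames(v, name)), lt)
    res[[perspective]]$d_cost / res[[perspective]]$d_qaly
  }
  icer <- vapply(bounds, icer_at, numeric(1))
  data.frame(parameter = name, low = bounds[[1]], high = bounds[[2]],
             icer_low = icer[1], icer_high = icer[2],
             range = abs(icer[2] - icer[1]), row.names = NULL)
}

#' Tornado analysis over a set of parameters
#'
#' Runs [one_way()] for every named parameter (default: all parameters with
#' sampling uncertainty) and sorts the entries by the absolute ICER spread.
#'
#' @inheritParams one_way
#' @param names Parameters to vary; defaults to all with `se > 0`.
#' @return Data frame of one-way entries, widest spread first.
#' @export
tornado_analysis <- function(params, lt, names = NULL,
                             perspective = c("societal", "payer"),
                             level = 0.95) {
  perspective <- match.arg(perspective)
  if (is.null(names)) {
    names <- params$specs$name[params$specs$se > 0 &
                                 params$specs$family != "fixed"]
  }
  unknown <- setdiff(names, params$specs$name)
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         "; valid names are: ", paste(params$specs$name, collapse = ", "))
  }
  out <- do.call(rbind, lapply(names, function(nm) {
    one_way(params, lt, nm, perspective = perspective, level = level)
  }))
  out[order(-out$range), , drop = FALSE]
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo resampling of every uncertain parameter from its assigned
#' distribution (beta for probabilities and utilities, gamma for costs;
#' parameters sampled independently), re-running both arms per draw and
#' recording the incremental cost (both perspectives), QALYs and life
#' years. Deterministic given the seed: each parameter draws from its own
#' substream keyed on the master seed and the parameter name. Distribution
#' feasibility is checked at setup, before any model run.
#'
#' @param params A `param_set`.
#' @param lt A `life_table`.
#' @param n_draws Number of Monte Carlo draws (published analysis: 1,000).
#' @param seed Master seed; defaults to the configured one.
#' @return A `psa_result`: list with `draws` (data frame: `draw`,
#'   `inc_cost_payer`, `inc_cost_societal`, `inc_qaly`, `inc_ly`), `n`,
#'   `seed`, and `summary` (per perspective: mean increments, the
#'   ratio-of-means ICER, and cost-effectiveness-plane quadrant fractions).
#' @export
run_psa <- function(params, lt, n_draws = params$config$psa_draws,
                    seed = params$config$seed) {
  stopifnot(n_draws >= 1)
  # setup-time feasibility check of every sampled distribution
  for (i in seq_len(nrow(params$specs))) {
    sp <- params$specs[i, ]
    if (sp$se == 0 || sp$family == "fixed") next
    if (sp$family == "beta") beta_from_moments(sp$mean, sp$se, sp$name)
    else gamma_from_moments(sp$mean, sp$se, sp$name)
  }
  draws <- sample_parameter_draws(params, n_draws, seed)
  res <- matrix(NA_real_, n_draws, 4,
                dimnames = list(NULL, c("inc_cost_payer", "inc_cost_societal",
                                        "inc_qaly", "inc_ly")))
  for (d in seq_len(n_draws)) {
    ps_d <- set_param_values(params, draws[d, ])
    s <- evaluate_arm("surgery", ps_d, lt)
    n <- evaluate_arm("nonsurgery", ps_d, lt)
    res[d, ] <- c(s$cost_payer - n$cost_payer,
                  s$cost_societal - n$cost_societal,
                  s$qaly - n$qaly, s$ly - n$ly)
  }
  df <- data.frame(draw = seq_len(n_draws), res)
  summ <- lapply(c(payer = "inc_cost_payer", societal = "inc_cost_societal"),
                 function(col) {
    dc <- df[[col]]; dq <- df$inc_qaly
    list(mean_inc_cost = mean(dc), mean_inc_qaly = mean(dq),
         icer = if (mean(dq) != 0) mean(dc) / mean(dq) else NA_real_,
         quadrants = c(
           ne = mean(dc > 0 & dq > 0),   # costlier, more effective
           se = mean(dc <= 0 & dq > 0),  # cost-saving, more effective
           sw = mean(dc <= 0 & dq <= 0),
           nw = mean(dc > 0 & dq <= 0)))
  })
  structure(list(draws = df, n = n_draws, seed = seed, summary = summ),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary$societal
  cat(sprintf(paste0("<psa_result> %d draws (seed %s)\n  societal: mean dCost ",
                     "%.2f, mean dQALY %.3f, ICER %.2f baht/QALY\n  ",
                     "cost-saving & more effective: %.1f%% of draws\n"),
              x$n, format(x$seed), s$mean_inc_cost, s$mean_inc_qaly, s$icer,
              100 * s$quadrants[["se"]]))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention is cost-effective at each
#' willingness-to-pay value: the fraction of draws with non-negative net
#' monetary benefit, `wtp * dQALY - dCost >= 0`. At `wtp = 0` this is the
#' fraction of cost-saving draws.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Willingness-to-pay grid (baht/QALY).
#' @param perspective `"payer"` or `"societal"`.
#' @return Data frame with `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 320000, by = 8000),
                 perspective = c("societal", "payer")) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa$draws) > 0)
  perspective <- match.arg(perspective)
  dc <- psa$draws[[if (perspective == "payer") "inc_cost_payer"
                   else "inc_cost_societal"]]
  dq <- psa$draws$inc_qaly
  prob <- vapply(wtp_grid, function(l) mean(l * dq - dc >= 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}
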