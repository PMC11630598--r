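# Method-of-moments parameterisation of the beta and gamma families used to
# resample probabilities/utilities and costs, plus seeded per-parameter
# sampling streams.

#' Beta shape parameters from a mean and standard error
#'
#' Method of moments: with `k = mean*(1-mean)/se^2 - 1`,
#' `shape1 = mean*k` and `shape2 = (1-mean)*k`. The returned shapes
#' reproduce the input mean and SE exactly.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error; must satisfy `0 < se^2 < mean*(1-mean)`.
#' @param name Optional parameter name used in error messages.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @export
beta_from_moments <- function(mean, se, name = NULL) {
  lab <- if (is.null(name)) "" else paste0(" for '", name, "'")
  if (mean <= 0 || mean >= 1) {
    stop("beta mean must lie strictly in (0, 1)", lab)
  }
  if (se <= 0) stop("beta SE must be positive", lab)
  if (se^2 >= mean * (1 - mean)) {
    stop("infeasible beta variance (se^2 >= mean*(1-mean))", lab)
  }
  k <- mean * (1 - mean) / se^2 - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Gamma shape and scale from a mean and standard error
#'
#' Method of moments: `shape = mean^2/se^2`, `scale = se^2/mean`; the
#' returned pair reproduces the input moments exactly. `se = mean` gives
#' shape 1 (an exponential), which does occur among interview-derived cost
#' parameters and is accepted.
#'
#' @param mean Positive mean.
#' @param se Positive standard error.
#' @param name Optional parameter name used in error messages.
#' @return Named numeric vector `c(shape, scale)`.
#' @export
gamma_from_moments <- function(mean, se, name = NULL) {
  lab <- if (is.null(name)) "" else paste0(" for '", name, "'")
  if (mean <= 0) stop("gamma mean must be positive", lab)
  if (se <= 0) stop("gamma SE must be positive", lab)
  c(shape = mean^2 / se^2, scale = se^2 / mean)
}

# Deterministic 31-bit stream seed derived from a master seed and a
# parameter name, so each parameter owns an independent substream and
# adding a parameter does not perturb the draws of the others.
substream_seed <- function(seed, name) {
  s <- as.numeric(seed) %% 2147483629
  for (ch in utf8ToInt(name)) s <- (s * 31 + ch) %% 2147483629
  as.integer(s)
}

#' Sample one parameter from its assigned distribution
#'
#' Draws from the beta (probabilities, utilities) or gamma (costs) family
#' parameterised by moments; parameters with `family = "fixed"` or a zero SE
#' are treated as degenerate and returned as constants (with a message, so
#' the run log records them).
#'
#' @param spec One-row parameter spec (see [param_spec()]).
#' @param n Number of draws.
#' @param seed Master seed; the actual stream is a substream keyed by the
#'   parameter name.
#' @return Numeric vector of length `n`.
#' @export
sample_parameter <- function(spec, n, seed) {
  stopifnot(nrow(spec) == 1, n >= 1)
  if (spec$family == "fixed" || spec$se == 0) {
    message("parameter '", spec$name, "' has no sampling uncertainty; ",
            "treated as fixed")
    return(rep(spec$mean, n))
  }
  set.seed(substream_seed(seed, spec$name))
  if (spec$family == "beta") {
    sh <- beta_from_moments(spec$mean, spec$se, spec$name)
    stats::rbeta(n, sh[["shape1"]], sh[["shape2"]])
  } else {
    sh <- gamma_from_moments(spec$mean, spec$se, spec$name)
    stats::rgamma(n, shape = sh[["shape"]], scale = sh[["scale"]])
  }
}

#' Draw a joint sample of all parameters
#'
#' Independently samples every parameter in the set (no correlation
#' structure is imposed). Fixed / zero-SE parameters are held at their
#' means.
#'
#' @param ps A `param_set`.
#' @param n Number of joint draws.
#' @param seed Master seed.
#' @return An `n` x `n_parameters` matrix with parameter names as columns.
#' @export
sample_parameter_draws <- function(ps, n, seed) {
  specs <- ps$specs
  out <- matrix(NA_real_, nrow = n, ncol = nrow(specs),
                dimnames = list(NULL, specs$name))
  for (i in seq_len(nrow(specs))) {
    out[, i] <- suppressMessages(sample_parameter(specs[i, ], n, seed))
  }
  out
}

#' Central interval of a parameter's assigned distribution
#'
#' Used to set one-way sensitivity bounds (default the 2.5th/97.5th
#' percentiles). Fixed / zero-SE parameters return a zero-width interval at
#' the mean.
#'
#' @param spec One-row parameter spec.
#' @param level Coverage, default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
parameter_interval <- function(spec, level = 0.95) {
  stopifnot(nrow(spec) == 1, level > 0, level < 1)
  if (spec$family == "fixed" || spec$se == 0) {
    return(c(low = spec$mean, high = spec$mean))
  }
  p <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (spec$family == "beta") {
    sh <- beta_from_moments(spec$mean, spec$se, spec$name)
    q <- stats::qbeta(p, sh[["shape1"]], sh[["shape2"]])
  } else {
    sh <- gamma_from_moments(spec$mean, spec$se, spec$name)
    q <- stats::qgamma(p, shape = sh[["shape"]], scale = sh[["scale"]])
  }
  c(low = q[1], high = q[2])
}
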