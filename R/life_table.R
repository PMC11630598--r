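# Background mortality: an age-indexed life table of annual all-cause death
# probabilities, adjusted by the mortality rate ratio of obesity with T2DM.

#' Construct a life table
#'
#' @param table Data frame with integer column `age` (contiguous) and column
#'   `q`, the annual all-cause death probability in `[0, 1]`.
#' @param rr Mortality rate ratio applied multiplicatively to `q` (capped at
#'   1). Applied identically in remission and non-remission states: glycaemic
#'   remission is assumed not to change all-cause mortality.
#' @return An object of class `life_table`.
#' @export
life_table <- function(table, rr = 1) {
  stopifnot(is.data.frame(table), all(c("age", "q") %in% names(table)))
  table <- table[order(table$age), c("age", "q")]
  if (any(diff(table$age) != 1)) stop("life table ages must be contiguous")
  if (any(table$q < 0 | table$q > 1)) stop("q must lie in [0, 1]")
  if (rr <= 0) stop("rr must be positive")
  structure(list(table = table, rr = rr), class = "life_table")
}

#' Load a life table from CSV
#'
#' @param path CSV with columns `age`, `q`.
#' @param rr Mortality rate ratio, see [life_table()].
#' @return A `life_table`.
#' @export
load_life_table <- function(path, rr = 1) {
  stopifnot(file.exists(path))
  life_table(utils::read.csv(path, comment.char = "#"), rr = rr)
}

#' Packaged synthetic life table
#'
#' The Gompertz-generated background mortality fixture shipped with the
#' package (see [generate_life_table()] for its construction). A synthetic
#' stand-in: the published national life table is not reproduced here.
#'
#' @param rr Mortality rate ratio to attach.
#' @return A `life_table`.
#' @export
default_life_table <- function(rr = default_run_config()$rr_mortality) {
  load_life_table(system.file("extdata", "life_table_synthetic.csv",
                              package = "bariaCEA"), rr = rr)
}

#' Rate-ratio-adjusted annual death probability at a given age
#'
#' Returns `min(1, q(age) * rr)`. Ages above the table range are clamped to
#' the last row with a warning; ages below the range are an error.
#'
#' @param lt A `life_table`.
#' @param age Age(s) in years.
#' @param rr Rate ratio override; defaults to the ratio attached to `lt`.
#' @return Adjusted annual death probability, same length as `age`.
#' @export
background_mortality <- function(lt, age, rr = lt$rr) {
  stopifnot(inherits(lt, "life_table"))
  tab <- lt$table
  if (any(age < min(tab$age))) stop("age below life-table range")
  if (any(age > max(tab$age))) {
    warning("age above life-table range; clamped to the last row")
    age <- pmin(age, max(tab$age))
  }
  q <- tab$q[match(floor(age), tab$age)]
  pmin(1, q * rr)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> ages %d-%d, rr = %.2f, q range [%.2e, %.3f]\n",
              min(x$table$age), max(x$table$age), x$rr,
              min(x$table$q), max(x$table$q)))
  invisible(x)
}

#' Life expectancy implied by a life table
#'
#' Discrete-time life expectancy at `age`: the sum of survival probabilities
#' over subsequent whole years plus a half-year for the death year.
#'
#' @param lt A `life_table`.
#' @param age Starting age.
#' @param rr Rate ratio override.
#' @return Expected remaining years.
#' @export
life_expectancy <- function(lt, age = 0, rr = lt$rr) {
  tab <- lt$table
  ages <- tab$age[tab$age >= age]
  q <- pmin(1, tab$q[tab$age >= age] * rr)
  sum(cumprod(1 - q)) + 0.5
}
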