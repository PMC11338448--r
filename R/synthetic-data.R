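#' Laplace (double-exponential) random deviates
#'
#' Density \eqn{f(z) = \exp(-|z - \mu|/b)/(2b)}; drawn by inverse CDF.
#'
#' @param n Number of draws.
#' @param location,scale Location \eqn{\mu} and scale \eqn{b > 0}.
#' @return Numeric vector of length `n`.
#' @export
rlaplace <- function(n, location = 0, scale = 1) {
  stopifnot(scale > 0)
  u <- stats::runif(n) - 0.5
  location - scale * sign(u) * log1p(-2 * abs(u))
}

# The four base distributions of the simulation design. All have unit
# scale: normal variance 1, exponential rate 1, Cauchy and Laplace scale 1.
wmw_distributions <- c("normal", "exponential", "cauchy", "laplace")

#' Draw one group of observations for the simulation design
#'
#' `n` i.i.d. draws from one of the four study distributions, then shifted
#' by a location offset `shift`. The shift is applied to the raw draws,
#' before any rounding: rounding models the measuring instrument, which
#' sees the shifted values. For the Cauchy, which has no mean, `shift`
#' offsets the location parameter.
#'
#' @param distribution One of `"normal"` (mean 0, variance 1),
#'   `"exponential"` (rate 1), `"cauchy"` (location 0, scale 1),
#'   `"laplace"` (location 0, scale 1).
#' @param shift Location shift added to every draw.
#' @param n Number of observations.
#' @return Numeric vector of length `n`. Uses the current RNG state; call
#'   [set.seed()] for reproducibility.
#' @export
draw_group <- function(distribution = wmw_distributions, shift = 0, n) {
  distribution <- match.arg(distribution)
  stopifnot(n >= 1)
  shift + switch(distribution,
    normal      = stats::rnorm(n),
    exponential = stats::rexp(n),
    cauchy      = stats::rcauchy(n),
    laplace     = rlaplace(n))
}

#' Define a simulation scenario
#'
#' One cell of the simulation grid: a base distribution, a pure location
#' shift applied to group 2, the two group sizes, the number of decimal
#' places to which measurements are rounded (the tie-generating mechanism),
#' and the nominal significance levels at which rejections are counted.
#' `shift = 0` is a null (type-I error) scenario, `shift > 0` a power
#' scenario.
#'
#' @inheritParams draw_group
#' @param n1,n2 Group sizes.
#' @param decimals Decimal places kept when rounding (1 or 2 in the
#'   replicated study design; any non-negative integer is accepted).
#' @param alphas Nominal significance levels.
#' @return A list of class `"wmw_scenario"`.
#' @examples
#' wmw_scenario("exponential", shift = 1, n1 = 10, n2 = 10, decimals = 1)
#' @export
wmw_scenario <- function(distribution = wmw_distributions, shift = 0,
                         n1 = 10L, n2 = 10L, decimals = 2L,
                         alphas = c(0.05, 0.01)) {
  distribution <- match.arg(distribution)
  stopifnot(n1 >= 1, n2 >= 1, shift >= 0, decimals >= 0, all(alphas > 0))
  structure(
    list(distribution = distribution, shift = shift,
         n1 = as.integer(n1), n2 = as.integer(n2),
         decimals = as.integer(decimals), alphas = alphas),
    class = "wmw_scenario")
}

#' @export
print.wmw_scenario <- function(x, ...) {
  cat(sprintf("Scenario: %s, shift %g, n1 = %d, n2 = %d, %d decimal(s), alpha = %s\n",
              x$distribution, x$shift, x$n1, x$n2, x$decimals,
              paste(x$alphas, collapse = "/")))
  invisible(x)
}

#' Draw one two-sample data set under a scenario
#'
#' Group 1 from the base distribution, group 2 from the base distribution
#' shifted by the scenario's location offset; both groups then rounded to
#' the scenario's number of decimal places ([round_values()]), which is
#' what creates ties.
#'
#' @param scenario A [wmw_scenario()].
#' @return A list with numeric components `x` and `y`.
#' @export
draw_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "wmw_scenario"))
  list(x = round_values(draw_group(scenario$distribution, 0, scenario$n1),
                        scenario$decimals),
       y = round_values(draw_group(scenario$distribution, scenario$shift,
                                   scenario$n2),
                        scenario$decimals))
}
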