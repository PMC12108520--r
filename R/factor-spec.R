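#' Define a factor marginal for the herd simulator
#'
#' A factor spec describes one simulated covariate: its support
#' `[lower, upper]`, the target moments of the *truncated* distribution,
#' and the distribution family used to realise them.
#'
#' Three families are available:
#' \describe{
#'   \item{`"skew_normal"`}{A skew-normal distribution truncated to
#'     `[lower, upper]`. Location, scale and slant are solved by
#'     root-finding so that the truncated mean and SD match `mean` and
#'     `sd` exactly, and the truncated skewness comes as close to
#'     `skewness` as the family allows. One family covers both left- and
#'     right-skewed marginals.}
#'   \item{`"geometric"`}{A geometric distribution truncated to the
#'     integers `lower, ..., upper`, with success probability solved so
#'     the truncated mean matches `mean`. Intended for parity-like
#'     counts; `sd` may be `NA` (it is implied by the family).}
#'   \item{`"exponential"`}{An exponential distribution truncated to
#'     `[lower, upper]`, rate solved so the truncated mean matches
#'     `mean`. Intended for strongly right-concentrated durations;
#'     `sd` may be `NA`.}
#' }
#'
#' @param name Identifier for the factor (used in error messages and as
#'   the column name downstream).
#' @param lower,upper Support bounds, in the factor's units
#'   (`lower < upper`).
#' @param mean Target mean of the truncated distribution
#'   (`lower <= mean <= upper`).
#' @param sd Target standard deviation (`> 0`); may be `NA` for the
#'   `"geometric"` and `"exponential"` families, whose dispersion is
#'   implied by the mean.
#' @param skewness Target skewness of the truncated distribution; use 0
#'   when unknown. Only honoured by `"skew_normal"`.
#' @param family Distribution family, see Details.
#' @param integer_valued If `TRUE`, sampled values are integers (exact
#'   for `"geometric"`; nearest-integer rounding otherwise).
#' @return An object of class `factor_spec`.
#' @export
#' @examples
#' factor_spec("temperature_c", 2.2, 38.8, mean = 22.781, sd = 7.775,
#'             skewness = -0.15)
factor_spec <- function(name, lower, upper, mean, sd = NA_real_,
                        skewness = 0,
                        family = c("skew_normal", "geometric", "exponential"),
                        integer_valued = FALSE) {
  family <- match.arg(family)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    abort(sprintf("factor '%s': need lower < upper, got [%s, %s]",
                  name, lower, upper))
  }
  if (!is.finite(mean) || mean < lower || mean > upper) {
    abort(sprintf("factor '%s': mean %s outside [%s, %s]",
                  name, mean, lower, upper))
  }
  if (family == "skew_normal") {
    if (!is.finite(sd) || sd <= 0) {
      abort(sprintf("factor '%s': skew_normal family needs sd > 0", name))
    }
  } else if (is.finite(sd) && sd <= 0) {
    abort(sprintf("factor '%s': sd must be > 0 when given", name))
  }
  structure(
    list(name = name, lower = lower, upper = upper, mean = mean,
         sd = sd, skewness = skewness, family = family,
         integer_valued = isTRUE(integer_valued)),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf(
    "<factor_spec> %s: %s on [%g, %g], mean %g, sd %s, skew %g%s\n",
    x$name, x$family, x$lower, x$upper, x$mean,
    ifelse(is.na(x$sd), "NA", format(x$sd)), x$skewness,
    if (x$integer_valued) ", integer" else ""
  ))
  invisible(x)
}

#' Reference factor marginals for a commercial Holstein herd
#'
#' The calibration bundled with the package: marginal moments, bounds and
#' skewness of the six herd factors as reported for a two-year record set
#' (17 500 cow-day records) from a large-scale Holstein dairy operation.
#' Lactation number is a truncated-geometric parity count (its reported
#' dispersion and quartiles are not internally consistent with the 1-8
#' range, so only mean and range are used); gestation day is a
#' truncated-exponential duration concentrated at small values; the
#' remaining factors are truncated skew-normals.
#'
#' @return A named list of [factor_spec()] objects in canonical column
#'   order (see [herd_columns()]).
#' @export
#' @examples
#' herd_factor_specs()$temperature_c
herd_factor_specs <- function() {
  specs <- list(
    factor_spec("tmr_dm_pct", 46.77, 56.49, mean = 51.379, sd = 1.963,
                skewness = 1.18),
    factor_spec("lactation_number", 1, 8, mean = 2.252,
                family = "geometric", integer_valued = TRUE),
    factor_spec("lactation_day", 6, 350, mean = 166.20, sd = 90.87,
                skewness = 0.10),
    factor_spec("gestation_day", 1, 230, mean = 66.454,
                family = "exponential"),
    factor_spec("age_months", 22.3, 110, mean = 44.174, sd = 16.139,
                skewness = 1.25),
    factor_spec("temperature_c", 2.2, 38.8, mean = 22.781, sd = 7.775,
                skewness = -0.15)
  )
  setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Reference response marginals
#'
#' Marginal summary values of the two responses in the bundled reference
#' calibration: mean, SD, variance, and observed range of milk yield
#' (L/24 h) and dry-matter intake (units/cow). Used as generator targets
#' and as default desirability anchors.
#'
#' @return A tibble with one row per response.
#' @export
reference_response_marginals <- function() {
  tibble(
    response = HERD_RESPONSES,
    mean = c(51.856, 24.233),
    sd = c(8.999, 2.776),
    variance = c(80.979, 7.705),
    minimum = c(24.5, 14.51),
    maximum = c(70.4, 34.4)
  )
}
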