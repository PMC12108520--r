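#' Reference response-surface coefficients
#'
#' The bundled main-effects linear equations relating the six herd
#' factors to the two responses, estimated on the reference Holstein
#' record set. Order: intercept, then the factors in canonical order
#' (see [herd_columns()]).
#'
#' `milk_yield_coefficients()` is in L/24 h per factor unit: milk yield
#' falls with TMR dry-matter percentage, day of lactation, day of
#' gestation, age and temperature, and rises with parity.
#' `dm_intake_coefficients()` is in intake units/cow per factor unit.
#'
#' @return Named numeric vector of length 7.
#' @export
#' @examples
#' milk_yield_coefficients()
milk_yield_coefficients <- function() {
  c("(Intercept)" = 109.87,
    tmr_dm_pct = -0.9148,
    lactation_number = 3.753,
    lactation_day = -0.02229,
    gestation_day = -0.03834,
    age_months = -0.2440,
    temperature_c = -0.10651)
}

#' @rdname milk_yield_coefficients
#' @export
dm_intake_coefficients <- function() {
  c("(Intercept)" = 16.202,
    tmr_dm_pct = 0.15626,
    lactation_number = 0.1311,
    lactation_day = 0.017244,
    gestation_day = -0.013458,
    age_months = -0.00891,
    temperature_c = 0.08213)
}
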