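#' Point prediction with confidence and prediction intervals
#'
#' Evaluates a fitted model at one factor setting and returns the fitted
#' mean, its standard error, the confidence interval for the mean
#' response and the prediction interval for a single new observation:
#' `fit = x0' beta`, `se_fit = sqrt(x0' Cov x0)`,
#' `CI = fit +/- t se_fit`, `PI = fit +/- t sqrt(s^2 + se_fit^2)` with
#' `t` the `(1 + level)/2` quantile on the residual df (normal quantile
#' when df is infinite, as for a [fixed_herd_model()]). The CI is always
#' nested inside the PI, strictly so when the residual variance is
#' positive.
#'
#' @param model A `herd_lm`.
#' @param settings Named numeric vector (or one-row data frame) giving a
#'   value for every model term; interaction columns are derived
#'   automatically.
#' @param level Interval coverage, default 0.95.
#' @return One-row tibble: `response`, `fit`, `se_fit`, `ci_low`,
#'   `ci_high`, `pi_low`, `pi_high`, `level`.
#' @export
#' @examples
#' m <- fixed_herd_model(milk_yield_coefficients(), response_name = "milk_yield")
#' predict_point(m, c(tmr_dm_pct = 46.77, lactation_number = 5,
#'                    lactation_day = 6, gestation_day = 230,
#'                    age_months = 55.8, temperature_c = 20))
predict_point <- function(model, settings, level = 0.95) {
  stopifnot(inherits(model, "herd_lm"), level > 0, level < 1)
  x0 <- design_point(model, settings)
  fit <- sum(x0 * model$coefficients)
  se_fit <- sqrt(max(drop(t(x0) %*% model$vcov %*% x0), 0))
  tq <- if (is.finite(model$df_residual)) {
    qt((1 + level) / 2, model$df_residual)
  } else {
    qnorm((1 + level) / 2)
  }
  se_pred <- sqrt(model$sigma2 + se_fit^2)
  tibble(
    response = model$response_name,
    fit = fit,
    se_fit = se_fit,
    ci_low = fit - tq * se_fit,
    ci_high = fit + tq * se_fit,
    pi_low = fit - tq * se_pred,
    pi_high = fit + tq * se_pred,
    level = level
  )
}

# expand named settings into the model's design-row, erroring on any
# missing factor; interaction columns are products of their parents
design_point <- function(model, settings) {
  if (is.data.frame(settings)) {
    stopifnot(nrow(settings) == 1L)
    settings <- unlist(settings[1, , drop = TRUE])
  }
  base_terms <- unique(unlist(strsplit(names(model$term_groups), ":", fixed = TRUE)))
  missing <- setdiff(base_terms, names(settings))
  if (length(missing)) {
    abort(paste0("predict_point: missing factor setting(s): ",
                 paste(missing, collapse = ", ")))
  }
  vapply(names(model$coefficients), function(nm) {
    if (nm == "(Intercept)") return(1)
    prod(settings[strsplit(nm, ":", fixed = TRUE)[[1]]])
  }, 0)
}
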