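#' Adjusted (Type-III) sums-of-squares ANOVA
#'
#' For every model term, the adjusted sum of squares is the increase in
#' residual sum of squares when that term alone is dropped from the full
#' model — `RSS(reduced) - RSS(full)` — so each term is judged given all
#' the others. Continuous predictors carry 1 df each; an interaction
#' term's columns are dropped together. F is the term's adjusted mean
#' square over the residual mean square, with p from the F distribution.
#' On orthogonal designs adjusted and sequential sums of squares
#' coincide; in general the adjusted sums of squares need not add up to
#' the regression sum of squares.
#'
#' Reported p-values are exact; for display in the classical style use
#' [format_anova()], which floors them at 0.001.
#'
#' @param model A `herd_lm` fitted by [fit_ols()] (must carry its design
#'   and response).
#' @return A tibble with one row per term plus a residual row:
#'   `term`, `df`, `adj_ss`, `adj_ms`, `f_value`, `p_value`.
#' @export
#' @examples
#' herd <- generate_herd(generator_config(n_records = 500, seed = 1))
#' anova_adjusted(fit_herd_model(herd, "milk_yield"))
anova_adjusted <- function(model) {
  stopifnot(inherits(model, "herd_lm"))
  if (is.null(model$design)) {
    abort("anova_adjusted needs a model fitted by fit_ols (design not stored)")
  }
  X <- model$design
  y <- model$response
  rss_full <- model$rss
  ms_res <- model$sigma2
  rows <- purrr::map_dfr(names(model$term_groups), function(term) {
    cols <- model$term_groups[[term]]
    keep <- setdiff(colnames(X), cols)
    reduced <- qr_rss(X[, keep, drop = FALSE], y)
    df <- length(cols)
    adj_ss <- max(reduced$rss - rss_full, 0)
    f <- (adj_ss / df) / ms_res
    tibble(term = term, df = df, adj_ss = adj_ss, adj_ms = adj_ss / df,
           f_value = f,
           p_value = pf(f, df, model$df_residual, lower.tail = FALSE))
  })
  dplyr::bind_rows(
    rows,
    tibble(term = "Residual", df = model$df_residual, adj_ss = rss_full,
           adj_ms = ms_res, f_value = NA_real_, p_value = NA_real_)
  )
}

#' Format an ANOVA table in the classical print style
#'
#' Rounds and floors p-values at 0.001 (printed as `"0.001"`), the
#' convention of classical statistical-package ANOVA listings. The
#' underlying [anova_adjusted()] values stay exact.
#'
#' @param anova_table Output of [anova_adjusted()].
#' @param digits Significant digits for SS/MS/F.
#' @return A tibble of character columns ready for printing/CSV.
#' @export
format_anova <- function(anova_table, digits = 6) {
  anova_table |>
    dplyr::mutate(
      adj_ss = signif(.data$adj_ss, digits),
      adj_ms = signif(.data$adj_ms, digits),
      f_value = signif(.data$f_value, digits),
      p_value = ifelse(is.na(.data$p_value), NA,
                       sprintf("%.3f", pmax(.data$p_value, 0.001)))
    )
}

#' Standardized effects and the significance cutoff
#'
#' The absolute t statistic of every non-intercept coefficient —
#' `|estimate| / SE` — sorted descending, plus the two-sided critical
#' value `t(1 - alpha/2, df_residual)` used as the reference line of a
#' Pareto chart of standardized effects. For 1-df terms the ranking is
#' identical to the ANOVA F ranking (`F = t^2`).
#'
#' @param model A fitted `herd_lm`.
#' @param alpha Significance level for the cutoff (default 0.05).
#' @return A tibble `term`, `t_abs`, `critical` (the cutoff, repeated).
#' @export
#' @examples
#' herd <- generate_herd(generator_config(n_records = 500, seed = 1))
#' standardized_effects(fit_herd_model(herd, "milk_yield"))
standardized_effects <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "herd_lm"))
  se <- sqrt(diag(model$vcov))
  keep <- names(model$coefficients) != "(Intercept)"
  if (any(se[keep] == 0)) {
    abort(paste0("standardized_effects: zero standard error for term(s): ",
                 paste(names(se)[keep & se == 0], collapse = ", ")))
  }
  tibble(
    term = names(model$coefficients)[keep],
    t_abs = unname(abs(model$coefficients[keep] / se[keep])),
    critical = qt(1 - alpha / 2, model$df_residual)
  ) |>
    dplyr::arrange(dplyr::desc(.data$t_abs))
}
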