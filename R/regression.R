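#' Build a main-effects design matrix
#'
#' Assembles the design matrix for a response: an all-ones intercept
#' column first, then the requested factor columns in the order given,
#' then (optionally) all pairwise interaction products appended after the
#' main effects.
#'
#' @param table Data frame of herd records.
#' @param response Name of the response column.
#' @param terms Character vector of factor columns (non-empty, unique).
#' @param interactions If `TRUE`, append elementwise products of every
#'   pair of listed terms.
#' @return A list with `design` (matrix with named columns), `response`
#'   (numeric vector) and `term_groups` (named list mapping each model
#'   term to its design columns).
#' @export
#' @examples
#' herd <- generate_herd(generator_config(n_records = 50, seed = 1))
#' d <- build_design(herd, "milk_yield", c("tmr_dm_pct", "age_months"))
#' dim(d$design)
build_design <- function(table, response, terms = herd_columns("factors"),
                         interactions = FALSE) {
  table <- as.data.frame(table)
  if (nrow(table) == 0L) abort("build_design: zero rows")
  if (length(terms) == 0L || anyDuplicated(terms)) {
    abort("terms must be non-empty and unique")
  }
  missing <- setdiff(c(response, terms), names(table))
  if (length(missing)) {
    abort(paste0("build_design: missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  X <- cbind("(Intercept)" = rep(1, nrow(table)),
             as.matrix(table[terms]))
  term_groups <- as.list(setNames(terms, terms))
  if (interactions && length(terms) >= 2L) {
    pairs <- utils::combn(terms, 2, simplify = FALSE)
    for (p in pairs) {
      nm <- paste(p, collapse = ":")
      X <- cbind(X, setNames(list(table[[p[1]]] * table[[p[2]]]), nm)[[1]])
      colnames(X)[ncol(X)] <- nm
      term_groups[[nm]] <- nm
    }
  }
  list(design = X, response = as.numeric(table[[response]]),
       term_groups = term_groups, response_name = response)
}

# QR solve shared by fit_ols and the reduced-model refits in
# anova_adjusted; errors on rank deficiency naming the offending columns
qr_rss <- function(X, y, want_beta = FALSE) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    abort(paste0("design is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")),
          class = "herdopt_rank_error")
  }
  res <- qr.resid(qx, y)
  out <- list(rss = sum(res^2), qr = qx, residuals = res)
  if (want_beta) out$beta <- qr.coef(qx, y)
  out
}

#' Fit an ordinary least-squares model to a design matrix
#'
#' Solves the least-squares problem by QR (orthogonal) decomposition —
#' never by inverting the normal equations — and returns the fitted
#' model: coefficients, coefficient covariance `s^2 (X'X)^{-1}`,
#' residual variance, residual degrees of freedom and R-squared. A
#' condition number above 1e8 triggers a warning; a rank-deficient
#' design is an error naming the collinear columns.
#'
#' @param design Output of [build_design()] (or a list with `design`,
#'   `response`, `term_groups`).
#' @return An object of class `herd_lm`; see also [tidy.herd_lm()],
#'   [glance.herd_lm()], [anova_adjusted()], [predict_point()].
#' @export
#' @examples
#' herd <- generate_herd(generator_config(n_records = 300, seed = 1))
#' fit <- fit_ols(build_design(herd, "milk_yield"))
#' glance(fit)
fit_ols <- function(design) {
  X <- design$design
  y <- design$response
  n <- nrow(X); p <- ncol(X)
  if (n <= p) {
    abort(sprintf("fit_ols: need more rows than design columns (n = %d, p = %d)",
                  n, p))
  }
  sol <- qr_rss(X, y, want_beta = TRUE)
  kappa_x <- kappa(X, exact = FALSE)
  if (is.finite(kappa_x) && kappa_x > 1e8) {
    warn(sprintf("design condition number %.3g exceeds 1e8; estimates may be unstable",
                 kappa_x))
  }
  df_residual <- n - p
  s2 <- sol$rss / df_residual
  R <- qr.R(sol$qr)
  piv <- sol$qr$pivot
  xtx_inv <- chol2inv(R)[order(piv), order(piv), drop = FALSE]
  vcov <- s2 * xtx_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  tss <- sum((y - mean(y))^2)
  structure(
    list(coefficients = sol$beta,
         vcov = vcov,
         sigma2 = s2,
         df_residual = df_residual,
         r_squared = if (tss > 0) 1 - sol$rss / tss else NA_real_,
         rss = sol$rss,
         nobs = n,
         term_groups = design$term_groups,
         response_name = design$response_name %||% "y",
         design = X,
         response = y),
    class = "herd_lm"
  )
}

#' Fit a herd response model from a record table
#'
#' Convenience wrapper: [build_design()] then [fit_ols()]. The default is
#' the main-effects model of all six herd factors; pairwise interactions
#' are available behind the `interactions` flag.
#'
#' @inheritParams build_design
#' @return A `herd_lm` object.
#' @export
#' @examples
#' herd <- generate_herd(generator_config(n_records = 500, seed = 1))
#' fit <- fit_herd_model(herd, "milk_yield")
#' tidy(fit)
fit_herd_model <- function(table, response, terms = herd_columns("factors"),
                           interactions = FALSE) {
  fit_ols(build_design(table, response, terms, interactions))
}

#' Construct a fixed (pre-estimated) linear model
#'
#' Wraps a known coefficient vector as a `herd_lm` so it can be used for
#' point prediction and optimization without refitting. The coefficient
#' covariance is zero and the residual variance defaults to zero, so
#' predictions are exact linear evaluations; supply `sigma2` and
#' `df_residual` to carry uncertainty.
#'
#' @param coefficients Named numeric vector, intercept (`"(Intercept)"`)
#'   first, then one entry per term.
#' @param sigma2 Residual variance (default 0).
#' @param df_residual Residual degrees of freedom (default `Inf`, which
#'   makes interval quantiles normal).
#' @param response_name Label for the response.
#' @return A `herd_lm` object.
#' @export
#' @examples
#' m <- fixed_herd_model(milk_yield_coefficients(), response_name = "milk_yield")
#' predict_point(m, c(tmr_dm_pct = 46.77, lactation_number = 5,
#'                    lactation_day = 6, gestation_day = 230,
#'                    age_months = 55.8, temperature_c = 20))
fixed_herd_model <- function(coefficients, sigma2 = 0, df_residual = Inf,
                             response_name = "response") {
  if (is.null(names(coefficients))) {
    abort("fixed_herd_model: coefficients must be named")
  }
  terms <- setdiff(names(coefficients), "(Intercept)")
  p <- length(coefficients)
  structure(
    list(coefficients = coefficients,
         vcov = matrix(0, p, p, dimnames = list(names(coefficients),
                                                names(coefficients))),
         sigma2 = sigma2,
         df_residual = df_residual,
         r_squared = NA_real_,
         rss = NA_real_,
         nobs = NA_integer_,
         term_groups = as.list(setNames(terms, terms)),
         response_name = response_name,
         design = NULL,
         response = NULL),
    class = "herd_lm"
  )
}

#' @export
print.herd_lm <- function(x, ...) {
  cat(sprintf("<herd_lm> %s ~ %s\n", x$response_name,
              paste(names(x$term_groups), collapse = " + ")))
  cat(equation_text(x), "\n")
  if (is.finite(x$r_squared)) {
    cat(sprintf("R-squared %.4f, residual SD %.4f on %d df\n",
                x$r_squared, sqrt(x$sigma2), x$df_residual))
  }
  invisible(x)
}

#' Broom-style coefficient table
#'
#' @param x A `herd_lm`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @exportS3Method generics::tidy
#' @export
tidy.herd_lm <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  stat <- ifelse(se > 0, x$coefficients / se, NA_real_)
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * pt(-abs(stat), x$df_residual))
  )
}

#' Broom-style model summary
#'
#' @param x A `herd_lm`.
#' @param ... Unused.
#' @return One-row tibble with `r.squared`, `sigma`, `df.residual`,
#'   `nobs`.
#' @exportS3Method generics::glance
#' @export
glance.herd_lm <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = sqrt(x$sigma2),
         df.residual = x$df_residual, nobs = x$nobs)
}

#' Render a fitted equation as text
#'
#' @param model A `herd_lm`.
#' @param digits Significant digits per coefficient.
#' @return A single string, e.g.
#'   `"milk_yield = 109.9 - 0.9148 tmr_dm_pct + ..."`.
#' @export
equation_text <- function(model, digits = 4) {
  b <- model$coefficients
  lead <- format(b[[1]], digits = digits)
  rest <- purrr::map_chr(seq_along(b)[-1], function(j) {
    sprintf(" %s %s %s", if (b[[j]] >= 0) "+" else "-",
            format(abs(b[[j]]), digits = digits), names(b)[j])
  })
  paste0(model$response_name, " = ", lead, paste(rest, collapse = ""))
}
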