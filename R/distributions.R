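# Distribution machinery behind sample_factor(): each family is reduced to
# a calibrated quantile function so that sampling (and rank-copula
# correlation) is a single inverse-CDF evaluation.

.calib_cache <- new.env(parent = emptyenv())

# skew-normal density, location xi, scale omega, slant alpha
dsn <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  2 / omega * dnorm(z) * pnorm(alpha * z)
}

# Gauss-Legendre nodes on [-1, 1], computed once and rescaled per window
.gl_base <- local({
  cache <- NULL
  function(n) {
    if (is.null(cache)) cache <<- pracma::gaussLegendre(n, -1, 1)
    cache
  }
})

# truncated skew-normal moments on [a, b] via Gauss-Legendre quadrature.
# The quadrature window is narrowed to the part of [a, b] carrying mass so
# very small scales (sd -> 0) keep full resolution.
tsn_moments <- function(xi, omega, alpha, a, b, n_nodes = 200L) {
  lo <- max(a, xi - 12 * omega)
  hi <- min(b, xi + 12 * omega)
  if (!(lo < hi)) {      # support barely overlaps [a,b]: extreme tail
    lo <- a
    hi <- b
  }
  base <- .gl_base(n_nodes)
  half <- (hi - lo) / 2
  gl <- list(x = lo + half * (base$x + 1), w = half * base$w)
  f <- dsn(gl$x, xi, omega, alpha)
  z0 <- sum(gl$w * f)
  if (!is.finite(z0) || z0 < 1e-250) {
    return(list(mass = 0, mean = NA_real_, sd = NA_real_, skew = NA_real_))
  }
  m1 <- sum(gl$w * gl$x * f) / z0
  m2 <- sum(gl$w * (gl$x - m1)^2 * f) / z0
  m3 <- sum(gl$w * (gl$x - m1)^3 * f) / z0
  list(mass = z0, mean = m1, sd = sqrt(m2), skew = m3 / m2^1.5)
}

# Solve (xi, omega) so the truncated mean/sd hit the targets, alpha fixed.
# Returns NULL when the solve does not reach the tolerance.
tsn_solve_location_scale <- function(spec, alpha, start = NULL) {
  target_m <- spec$mean
  target_s <- spec$sd
  if (is.null(start)) {
    delta <- alpha / sqrt(1 + alpha^2)
    mz <- delta * sqrt(2 / pi)
    sz <- sqrt(max(1 - mz^2, 1e-6))
    omega0 <- target_s / sz
    start <- c(target_m - omega0 * mz, log(omega0))
  }
  objective <- function(p) {
    mom <- tsn_moments(p[1], exp(p[2]), alpha, spec$lower, spec$upper)
    if (mom$mass <= 0 || !is.finite(mom$sd)) return(1e6)
    ((mom$mean - target_m) / target_s)^2 + ((mom$sd - target_s) / target_s)^2
  }
  fit <- optim(start, objective, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 800))
  fit <- optim(fit$par, objective, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 800))
  if (sqrt(fit$value) > 1e-5) return(NULL)
  list(xi = fit$par[1], omega = exp(fit$par[2]), par = fit$par)
}

calibrate_skew_normal <- function(spec) {
  solve_at <- local({
    warm <- NULL
    function(alpha) {
      sol <- tsn_solve_location_scale(spec, alpha, start = warm)
      if (is.null(sol)) sol <- tsn_solve_location_scale(spec, alpha)
      if (!is.null(sol)) warm <<- sol$par
      sol
    }
  })
  skew_gap <- function(alpha) {
    sol <- solve_at(alpha)
    if (is.null(sol)) return(Inf)
    mom <- tsn_moments(sol$xi, sol$omega, alpha, spec$lower, spec$upper)
    (mom$skew - spec$skewness)^2
  }
  if (abs(spec$skewness) < 1e-8) {
    best_alpha <- 0
  } else {
    # coarse scan, then a 1-d refine in the best bracket: the attainable
    # truncated skewness may fall short of the target, in which case the
    # closest member of the family is used.
    grid <- c(-15, -8, -4, -2, -1, -0.5, 0, 0.5, 1, 2, 4, 8, 15)
    gaps <- vapply(grid, skew_gap, 0)
    i <- which.min(gaps)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    best_alpha <- optimize(skew_gap, c(lo, hi), tol = 1e-3)$minimum
    if (skew_gap(best_alpha) > gaps[i]) best_alpha <- grid[i]
  }
  sol <- solve_at(best_alpha)
  if (is.null(sol)) {
    abort(sprintf(
      paste0("calibration failed for factor '%s': no truncated skew-normal ",
             "on [%g, %g] attains mean %g with sd %g"),
      spec$name, spec$lower, spec$upper, spec$mean, spec$sd
    ), class = "herdopt_calibration_error")
  }
  # numeric inverse CDF on a fine grid over the mass-carrying window
  lo <- max(spec$lower, sol$xi - 12 * sol$omega)
  hi <- min(spec$upper, sol$xi + 12 * sol$omega)
  if (!(lo < hi)) { lo <- spec$lower; hi <- spec$upper }
  xg <- seq(lo, hi, length.out = 4001L)
  fg <- dsn(xg, sol$xi, sol$omega, best_alpha)
  cg <- c(0, cumsum((fg[-1] + fg[-length(fg)]) / 2 * diff(xg)))
  cg <- cg / cg[length(cg)]
  keep <- c(TRUE, diff(cg) > 0)
  qfun <- stats::approxfun(cg[keep], xg[keep], rule = 2)
  list(family = "skew_normal", qfun = qfun,
       params = list(xi = sol$xi, omega = sol$omega, alpha = best_alpha))
}

calibrate_geometric <- function(spec) {
  k <- seq(ceiling(spec$lower), floor(spec$upper))
  if (length(k) < 2L) {
    abort(sprintf("calibration failed for factor '%s': integer support empty",
                  spec$name), class = "herdopt_calibration_error")
  }
  mean_at <- function(p) {
    w <- (1 - p)^(k - k[1])
    sum(k * w) / sum(w)
  }
  if (spec$mean <= k[1] || spec$mean >= mean(k)) {
    # truncated geometric mean spans (k_min, mean(k)) as p goes 1 -> 0
    if (spec$mean >= mean(k)) {
      abort(sprintf(
        "calibration failed for factor '%s': mean %g not attainable by a truncated geometric on {%d..%d}",
        spec$name, spec$mean, k[1], k[length(k)]
      ), class = "herdopt_calibration_error")
    }
  }
  p <- uniroot(function(p) mean_at(p) - spec$mean,
               c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  pmf <- (1 - p)^(k - k[1])
  pmf <- pmf / sum(pmf)
  cum <- cumsum(pmf)
  qfun <- function(u) {
    idx <- findInterval(u, cum, left.open = TRUE) + 1L
    k[pmin(idx, length(k))]
  }
  list(family = "geometric", qfun = qfun, params = list(p = p, support = k))
}

calibrate_exponential <- function(spec) {
  a <- spec$lower; b <- spec$upper; L <- b - a
  mid <- (a + b) / 2
  if (spec$mean >= mid || spec$mean <= a) {
    abort(sprintf(
      "calibration failed for factor '%s': truncated-exponential mean must lie in (%g, %g)",
      spec$name, a, mid
    ), class = "herdopt_calibration_error")
  }
  mean_at <- function(r) a + 1 / r - L / expm1(r * L)
  r <- uniroot(function(lr) mean_at(exp(lr)) - spec$mean,
               c(-15, 8), tol = 1e-13)$root
  r <- exp(r)
  zb <- -expm1(-r * L)  # 1 - exp(-rL)
  qfun <- function(u) a - log1p(-u * zb) / r
  list(family = "exponential", qfun = qfun, params = list(rate = r))
}

# calibrate once per spec; memoised because root-finding on truncated
# moments is the expensive part of generation
calibrate_factor <- function(spec) {
  key <- rlang::hash(unclass(spec))
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)
  calib <- switch(spec$family,
    skew_normal = calibrate_skew_normal(spec),
    geometric = calibrate_geometric(spec),
    exponential = calibrate_exponential(spec)
  )
  calib$spec <- spec
  assign(key, calib, envir = .calib_cache)
  calib
}

#' Draw factor values from a calibrated marginal
#'
#' Samples `n` values from the distribution described by a
#' [factor_spec()]: the family is calibrated by root-finding so the
#' *truncated* moments hit the spec targets (see [factor_spec()]), then
#' values are drawn by inverse-CDF from the current R random stream.
#' All values fall inside `[lower, upper]`; integer-valued specs yield
#' integers.
#'
#' @param spec A [factor_spec()].
#' @param n Number of draws (`>= 1`).
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' set.seed(1)
#' x <- sample_factor(herd_factor_specs()$temperature_c, 1000)
#' range(x)
sample_factor <- function(spec, n) {
  stopifnot(inherits(spec, "factor_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("n must be a single integer >= 1")
  }
  calib <- calibrate_factor(spec)
  x <- calib$qfun(runif(n))
  if (spec$integer_valued && spec$family != "geometric") {
    x <- round(x)
  }
  pmin(pmax(x, spec$lower), spec$upper)
}

# quantile transform used by the rank copula in generate_herd()
factor_quantile <- function(spec, u) {
  calib <- calibrate_factor(spec)
  x <- calib$qfun(u)
  if (spec$integer_valued && spec$family != "geometric") x <- round(x)
  pmin(pmax(x, spec$lower), spec$upper)
}
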