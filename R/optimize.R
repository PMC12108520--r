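#' Assemble a box-constrained multi-response optimization problem
#'
#' @param objectives List of [objective_spec()]s (typically two: maximize
#'   milk yield, minimize dry-matter intake).
#' @param lower,upper Named numeric vectors of box bounds, one entry per
#'   factor, `lower < upper` elementwise. Every objective model must use
#'   exactly these factors.
#' @param integer_factors Character vector of factors constrained to
#'   integer values.
#' @return An object of class `optimization_problem`.
#' @export
optimization_problem <- function(objectives, lower, upper,
                                 integer_factors = character()) {
  if (inherits(objectives, "objective_spec")) objectives <- list(objectives)
  stopifnot(length(objectives) >= 1L,
            all(vapply(objectives, inherits, TRUE, "objective_spec")))
  factors <- names(lower)
  if (is.null(factors) || !identical(sort(factors), sort(names(upper)))) {
    abort("lower and upper must be named vectors over the same factors")
  }
  upper <- upper[factors]
  if (any(lower >= upper)) {
    abort(paste0("need lower < upper for every factor; violated for: ",
                 paste(factors[lower >= upper], collapse = ", ")))
  }
  for (obj in objectives) {
    terms <- unique(unlist(strsplit(names(obj$model$term_groups), ":",
                                    fixed = TRUE)))
    if (!setequal(terms, factors)) {
      abort(sprintf("objective '%s' uses factors {%s} but the box covers {%s}",
                    obj$name, paste(sort(terms), collapse = ", "),
                    paste(sort(factors), collapse = ", ")))
    }
  }
  bad <- setdiff(integer_factors, factors)
  if (length(bad)) {
    abort(paste0("integer_factors not in the box: ", paste(bad, collapse = ", ")))
  }
  structure(
    list(objectives = objectives, lower = lower, upper = upper,
         factors = factors, integer_factors = integer_factors),
    class = "optimization_problem"
  )
}

#' The bundled herd optimization problem
#'
#' Maximize predicted milk yield and minimize predicted dry-matter
#' intake over the reference box: TMR dry matter 46.77-56.49 %,
#' lactation number 1-8 (integer), lactation day 6-350, gestation day
#' 1-230, age 22.3-110 months, temperature 2.2-38.8 C. Desirability
#' anchors default to each response's observed range
#' ([reference_response_marginals()]); bounds and anchors are
#' overridable.
#'
#' @param milk_model,dm_model `herd_lm` models for the two responses;
#'   default the fixed reference equations.
#' @param lower,upper Optional named bound overrides (merged into the
#'   defaults).
#' @param anchors Optional list with elements `milk_yield` and
#'   `dm_intake`, each `c(low, high)`.
#' @return An `optimization_problem`.
#' @export
#' @examples
#' res <- optimize_settings(herd_problem(), n_starts = 10, seed = 1)
#' tidy(res)
herd_problem <- function(milk_model = NULL, dm_model = NULL,
                         lower = NULL, upper = NULL, anchors = NULL) {
  milk_model <- milk_model %||%
    fixed_herd_model(milk_yield_coefficients(), response_name = "milk_yield")
  dm_model <- dm_model %||%
    fixed_herd_model(dm_intake_coefficients(), response_name = "dm_intake")
  lb <- c(tmr_dm_pct = 46.77, lactation_number = 1, lactation_day = 6,
          gestation_day = 1, age_months = 22.3, temperature_c = 2.2)
  ub <- c(tmr_dm_pct = 56.49, lactation_number = 8, lactation_day = 350,
          gestation_day = 230, age_months = 110, temperature_c = 38.8)
  if (!is.null(lower)) lb[names(lower)] <- lower
  if (!is.null(upper)) ub[names(upper)] <- upper
  marg <- reference_response_marginals()
  anc <- list(
    milk_yield = c(marg$minimum[1], marg$maximum[1]),
    dm_intake = c(marg$minimum[2], marg$maximum[2])
  )
  if (!is.null(anchors)) anc[names(anchors)] <- anchors
  optimization_problem(
    objectives = list(
      objective_spec(milk_model, "maximize", anc$milk_yield[1],
                     anc$milk_yield[2], name = "milk_yield"),
      objective_spec(dm_model, "minimize", anc$dm_intake[1],
                     anc$dm_intake[2], name = "dm_intake")
    ),
    lower = lb, upper = ub, integer_factors = "lactation_number"
  )
}

# vectorised evaluation of composite desirability over a settings matrix
# (rows = points, columns = problem$factors)
eval_matrix <- function(problem, M) {
  n <- nrow(M)
  logd_w <- matrix(0, n, length(problem$objectives))
  zero <- rep(FALSE, n)
  imp <- vapply(problem$objectives, `[[`, 0, "importance")
  preds <- matrix(0, n, length(problem$objectives))
  for (j in seq_along(problem$objectives)) {
    obj <- problem$objectives[[j]]
    b <- obj$model$coefficients
    yhat <- rep(b[["(Intercept)"]], n)
    for (nm in names(b)) {
      if (nm == "(Intercept)") next
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      col <- M[, parts[1]]
      if (length(parts) > 1L) for (p in parts[-1]) col <- col * M[, p]
      yhat <- yhat + b[[nm]] * col
    }
    d <- desirability(yhat, obj$goal, obj$anchor_low, obj$anchor_high,
                      obj$weight)
    preds[, j] <- yhat
    zero <- zero | d == 0
    logd_w[, j] <- imp[j] * log(pmax(d, 1e-300))
  }
  D <- exp(rowSums(logd_w) / sum(imp))
  D[zero] <- 0
  list(D = D, predictions = preds)
}

#' Evaluate factor settings against an optimization problem
#'
#' Predicts every objective at the given in-box settings and returns the
#' individual and composite desirabilities.
#'
#' @param problem An [optimization_problem()].
#' @param settings Named numeric vector (or one-row data frame) inside
#'   the box.
#' @return A list with `settings`, `responses` (tibble: `objective`,
#'   `goal`, `prediction`, `desirability`) and `composite` (the scalar
#'   `D`).
#' @export
#' @examples
#' pr <- herd_problem()
#' evaluate_settings(pr, c(tmr_dm_pct = 46.77, lactation_number = 5,
#'   lactation_day = 6, gestation_day = 230, age_months = 55.8,
#'   temperature_c = 20))
evaluate_settings <- function(problem, settings) {
  stopifnot(inherits(problem, "optimization_problem"))
  if (is.data.frame(settings)) settings <- unlist(settings[1, , drop = TRUE])
  missing <- setdiff(problem$factors, names(settings))
  if (length(missing)) {
    abort(paste0("evaluate_settings: missing factor(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- settings[problem$factors]
  out_of_box <- x < problem$lower - 1e-9 | x > problem$upper + 1e-9
  if (any(out_of_box)) {
    abort(paste0("settings outside the box for: ",
                 paste(problem$factors[out_of_box], collapse = ", ")))
  }
  ev <- eval_matrix(problem, matrix(x, 1, dimnames = list(NULL, problem$factors)))
  ds <- vapply(seq_along(problem$objectives), function(j) {
    obj <- problem$objectives[[j]]
    desirability(ev$predictions[1, j], obj$goal, obj$anchor_low,
                 obj$anchor_high, obj$weight)
  }, 0)
  list(
    settings = x,
    responses = tibble(
      objective = vapply(problem$objectives, `[[`, "", "name"),
      goal = vapply(problem$objectives, `[[`, "", "goal"),
      prediction = ev$predictions[1, ],
      desirability = ds
    ),
    composite = ev$D[1]
  )
}

# projected compass (pattern) search: derivative-free, bounded, and
# monotone in D across iterations
compass_search <- function(problem, x0, free = problem$factors,
                           max_iter = 400L) {
  lb <- problem$lower; ub <- problem$upper
  x <- pmin(pmax(x0, lb), ub)
  f_x <- eval_matrix(problem, matrix(x, 1, dimnames = list(NULL, problem$factors)))$D
  h <- 0.25 * (ub - lb)
  free_idx <- match(free, problem$factors)
  for (iter in seq_len(max_iter)) {
    cand <- matrix(rep(x, 2L * length(free_idx)), ncol = length(x),
                   byrow = TRUE, dimnames = list(NULL, problem$factors))
    r <- 1L
    for (j in free_idx) {
      cand[r, j] <- min(x[j] + h[j], ub[j]); r <- r + 1L
      cand[r, j] <- max(x[j] - h[j], lb[j]); r <- r + 1L
    }
    D <- eval_matrix(problem, cand)$D
    best <- which.max(D)
    if (D[best] > f_x + 1e-14) {
      x <- cand[best, ]
      f_x <- D[best]
    } else {
      h <- h / 2
      if (max(h[free_idx] / (ub[free_idx] - lb[free_idx])) < 1e-10) break
    }
  }
  list(x = x, D = f_x)
}

#' Maximize composite desirability over the box
#'
#' Multi-start derivative-free search: a projected compass (pattern)
#' search is run from every vertex of the box's 2-level design plus
#' `n_starts` seeded random interior points; the terminal point with the
#' highest composite desirability wins. Ties (within 1e-12 in `D`) are
#' broken by distance to the box centre, then by start order. Integer
#' factors are relaxed during the search and finished by exhaustive
#' comparison of the neighbouring integer lattice points. Deterministic
#' given `seed`.
#'
#' @param problem An [optimization_problem()].
#' @param n_starts Number of random interior starts (default 20).
#' @param seed Integer seed for the random starts.
#' @param level Interval coverage for the per-objective predictions.
#' @return An object of class `herd_opt`: optimal `settings`,
#'   per-objective `responses` (prediction, desirability, SE/CI/PI via
#'   [predict_point()]), `composite` desirability and solver
#'   `diagnostics`. If every start terminates at `D = 0`, the best
#'   zero-desirability settings are returned flagged `converged = FALSE`.
#' @export
#' @examples
#' res <- optimize_settings(herd_problem(), n_starts = 10, seed = 1)
#' res$settings
#' tidy(res)
optimize_settings <- function(problem, n_starts = 20, seed = 1,
                              level = 0.95) {
  stopifnot(inherits(problem, "optimization_problem"))
  k <- length(problem$factors)
  lb <- problem$lower; ub <- problem$upper
  vertices <- as.matrix(expand.grid(purrr::map(seq_len(k), function(j) {
    c(lb[j], ub[j])
  })))
  colnames(vertices) <- problem$factors
  randoms <- withr::with_seed(seed, {
    matrix(runif(n_starts * k, rep(lb, each = n_starts),
                 rep(ub, each = n_starts)),
           n_starts, k, dimnames = list(NULL, problem$factors))
  })
  starts <- rbind(vertices, randoms)
  runs <- purrr::map(seq_len(nrow(starts)), function(i) {
    compass_search(problem, starts[i, ])
  })
  Ds <- vapply(runs, `[[`, 0, "D")
  centre <- (lb + ub) / 2
  dist2 <- vapply(runs, function(r) sum(((r$x - centre) / (ub - lb))^2), 0)
  ord <- order(-Ds, dist2, seq_along(runs))
  best <- runs[[ord[1]]]
  best_start <- ord[1]
  # integer finish: best neighbouring lattice point by exhaustive comparison
  if (length(problem$integer_factors)) {
    neigh <- purrr::map(problem$factors, function(f) {
      if (!f %in% problem$integer_factors) return(best$x[[f]])
      v <- unique(pmin(pmax(c(floor(best$x[[f]]), ceiling(best$x[[f]])),
                            ceiling(lb[[f]])), floor(ub[[f]])))
      v
    })
    grid <- as.matrix(expand.grid(neigh))
    colnames(grid) <- problem$factors
    D <- eval_matrix(problem, grid)$D
    j <- which.max(D)
    best <- list(x = grid[j, ], D = D[j])
  }
  ev <- evaluate_settings(problem, best$x)
  responses <- dplyr::bind_cols(
    ev$responses,
    purrr::map_dfr(problem$objectives, function(obj) {
      predict_point(obj$model, best$x, level = level)[
        , c("se_fit", "ci_low", "ci_high", "pi_low", "pi_high")]
    })
  )
  structure(
    list(settings = best$x,
         responses = responses,
         composite = ev$composite,
         diagnostics = list(
           n_starts = nrow(starts),
           best_start = best_start,
           converged = ev$composite > 0,
           level = level
         ),
         problem = problem),
    class = "herd_opt"
  )
}

#' Exhaustive grid-search oracle
#'
#' Evaluates the composite desirability on a regular grid including both
#' bounds in every factor and returns the exact grid argmax (ties broken
#' by the first point in row-major order, the first factor varying
#' fastest). Intended as an independent verification of
#' [optimize_settings()], not as a production solver.
#'
#' @param problem An [optimization_problem()].
#' @param points_per_dim Grid points per factor (`>= 2`); the full grid
#'   may not exceed 1e7 points.
#' @return A `herd_opt` object (diagnostics record the grid size).
#' @export
grid_oracle <- function(problem, points_per_dim = 21) {
  stopifnot(inherits(problem, "optimization_problem"), points_per_dim >= 2)
  k <- length(problem$factors)
  total <- points_per_dim^k
  if (total > 1e7) {
    abort(sprintf("grid too large: %d^%d = %.3g points (limit 1e7)",
                  points_per_dim, k, total))
  }
  axes <- purrr::map(seq_len(k), function(j) {
    seq(problem$lower[j], problem$upper[j], length.out = points_per_dim)
  })
  grid <- as.matrix(expand.grid(axes))
  colnames(grid) <- problem$factors
  D <- eval_matrix(problem, grid)$D
  j <- which.max(D)   # first maximum in row-major order
  ev <- evaluate_settings(problem, grid[j, ])
  structure(
    list(settings = grid[j, ],
         responses = ev$responses,
         composite = D[j],
         diagnostics = list(points_per_dim = points_per_dim,
                            grid_points = total, converged = D[j] > 0),
         problem = problem),
    class = "herd_opt"
  )
}

#' @export
print.herd_opt <- function(x, ...) {
  cat("<herd_opt> composite desirability D =", format(x$composite, digits = 6), "\n")
  cat("settings:\n")
  print(round(x$settings, 4))
  print(x$responses)
  invisible(x)
}

#' Tidy an optimization result
#'
#' @param x A `herd_opt`.
#' @param ... Unused.
#' @return Tibble of per-objective predictions, desirabilities and
#'   intervals, plus the composite desirability column.
#' @exportS3Method generics::tidy
#' @export
tidy.herd_opt <- function(x, ...) {
  dplyr::mutate(x$responses, composite = x$composite)
}

#' @rdname tidy.herd_opt
#' @exportS3Method generics::glance
#' @export
glance.herd_opt <- function(x, ...) {
  tibble(composite = x$composite,
         converged = x$diagnostics$converged,
         n_starts = x$diagnostics$n_starts %||% NA_integer_)
}
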