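#' Pareto chart of standardized effects
#'
#' Horizontal bars of the absolute t statistics from
#' [standardized_effects()], largest first, with the significance cutoff
#' as a dashed reference line.
#'
#' @param model A fitted `herd_lm`, or the tibble returned by
#'   [standardized_effects()].
#' @param alpha Significance level for the cutoff (used when `model` is
#'   a `herd_lm`).
#' @return A ggplot object.
#' @export
plot_pareto_effects <- function(model, alpha = 0.05) {
  effects <- if (inherits(model, "herd_lm")) {
    standardized_effects(model, alpha)
  } else {
    model
  }
  effects |>
    dplyr::mutate(term = stats::reorder(.data$term, .data$t_abs)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$t_abs, y = .data$term)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_vline(xintercept = effects$critical[1],
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "standardized effect |t|", y = NULL,
                  title = "Pareto chart of standardized effects",
                  subtitle = sprintf("reference line: |t| = %.3f",
                                     effects$critical[1])) +
    ggplot2::theme_minimal()
}

#' One-dimensional traces through the optimum
#'
#' For each factor, sweeps that factor across its box while holding the
#' others at the optimum, and draws every predicted response plus the
#' composite desirability — the standard response-optimizer panel.
#'
#' @param result A `herd_opt` from [optimize_settings()] or
#'   [grid_oracle()].
#' @param n_points Points per trace.
#' @return A ggplot object (facets: response/desirability by factor).
#' @export
plot_optimum_traces <- function(result, n_points = 60) {
  stopifnot(inherits(result, "herd_opt"))
  problem <- result$problem
  traces <- purrr::map_dfr(problem$factors, function(f) {
    xs <- seq(problem$lower[[f]], problem$upper[[f]], length.out = n_points)
    M <- matrix(rep(result$settings, each = n_points),
                n_points, dimnames = list(NULL, problem$factors))
    M[, f] <- xs
    ev <- eval_matrix(problem, M)
    out <- purrr::map_dfr(seq_along(problem$objectives), function(j) {
      tibble(factor = f, x = xs,
             panel = problem$objectives[[j]]$name,
             value = ev$predictions[, j])
    })
    dplyr::bind_rows(out, tibble(factor = f, x = xs,
                                 panel = "composite D", value = ev$D))
  })
  marks <- tibble(factor = problem$factors,
                  x = unname(result$settings[problem$factors]))
  ggplot2::ggplot(traces, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$x),
                        linetype = "dotted", colour = "red") +
    ggplot2::facet_grid(panel ~ factor, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Responses and composite desirability through the optimum") +
    ggplot2::theme_minimal()
}

#' @rdname plot_optimum_traces
#' @param object A `herd_opt`.
#' @param ... Passed to [plot_optimum_traces()].
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.herd_opt <- function(object, ...) plot_optimum_traces(object, ...)

#' Histogram panel of a herd-record table
#'
#' @param table Herd-record tibble.
#' @param bins Histogram bins.
#' @return A ggplot object faceted by variable.
#' @export
plot_herd_marginals <- function(table, bins = 40) {
  table |>
    dplyr::select(dplyr::any_of(herd_columns())) |>
    tidyr::pivot_longer(dplyr::everything()) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::facet_wrap(~name, scales = "free") +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}
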