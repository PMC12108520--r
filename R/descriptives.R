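#' Quartiles by the (n+1)p position rule
#'
#' First quartile, median and third quartile using linear interpolation
#' at position `(n+1) * p` between order statistics, with positions
#' clamped to `[1, n]` — the convention of classical statistical-package
#' output (R's `quantile()` type 6). Fixed to one convention so ports of
#' the same table agree to the last digit.
#'
#' @param values Numeric vector with at least one finite value.
#' @return Named numeric vector `c(q1, median, q3)`.
#' @export
#' @examples
#' quartiles(1:5) # 1.5, 3, 4.5
quartiles <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) abort("quartiles: no finite values")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

# adjusted Fisher-Pearson skewness / small-sample-adjusted excess
# kurtosis; NA (not 0) when the sample is too small or constant
safe_skewness <- function(x) {
  if (length(x) < 3L || sd(x) == 0) return(NA_real_)
  e1071::skewness(x, type = 2)
}
safe_kurtosis <- function(x) {
  if (length(x) < 4L || sd(x) == 0) return(NA_real_)
  e1071::kurtosis(x, type = 2)
}

#' Descriptive statistics of one variable
#'
#' The full descriptive panel for a numeric vector: n, mean, SE of the
#' mean, SD (n-1 denominator), variance, minimum, quartiles by the
#' `(n+1)p` rule ([quartiles()]), maximum, adjusted Fisher-Pearson
#' skewness and small-sample-adjusted excess kurtosis (0 for large
#' normal samples).
#'
#' Statistics that are undefined for a degenerate sample (dispersion
#' needs `n >= 2`, skewness `n >= 3`, kurtosis `n >= 4`) are an error by
#' default; with `allow_degenerate = TRUE` they are reported as `NA` —
#' an explicit not-available marker, never silently 0.
#'
#' @param values Numeric vector.
#' @param allow_degenerate Report undefined statistics as `NA` instead of
#'   erroring.
#' @return A one-row tibble.
#' @export
#' @examples
#' summary_stats(c(-2, -1, 0, 1, 2))
summary_stats <- function(values, allow_degenerate = FALSE) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) abort("summary_stats: no finite values")
  if (n < 2L && !allow_degenerate) {
    abort("summary_stats: n < 2, dispersion statistics undefined (set allow_degenerate = TRUE to report NA)")
  }
  q <- quartiles(values)
  s <- if (n >= 2L) sd(values) else NA_real_
  tibble(
    n = n,
    mean = mean(values),
    se_mean = s / sqrt(n),
    sd = s,
    variance = s^2,
    minimum = min(values),
    q1 = q[["q1"]],
    median = q[["median"]],
    q3 = q[["q3"]],
    maximum = max(values),
    skewness = safe_skewness(values),
    kurtosis = safe_kurtosis(values)
  )
}

#' Descriptive panel for a herd-record table
#'
#' Applies [summary_stats()] to every requested column, one row per
#' variable — the tidy form of the classic "statistic rows by variable
#' columns" panel (which [describe_panel()] produces for export).
#'
#' @param table A data frame of herd records.
#' @param vars Columns to summarise (character); default all numeric
#'   columns.
#' @param allow_degenerate Passed to [summary_stats()].
#' @return A tibble, one row per variable.
#' @export
#' @examples
#' herd <- generate_herd(generator_config(n_records = 300, seed = 1))
#' describe_herd(herd)
describe_herd <- function(table, vars = NULL, allow_degenerate = FALSE) {
  table <- as_tibble(table)
  if (is.null(vars)) {
    vars <- names(table)[vapply(table, is.numeric, TRUE)]
  }
  missing <- setdiff(vars, names(table))
  if (length(missing)) {
    abort(paste0("describe_herd: missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(vars, function(v) {
    dplyr::bind_cols(tibble(variable = v),
                     summary_stats(table[[v]], allow_degenerate))
  })
}

#' Pivot a descriptive panel to the classic layout
#'
#' Turns the output of [describe_herd()] into one row per statistic and
#' one column per variable, the layout used by printed descriptive
#' tables. `NA` markers survive as empty cells on CSV export.
#'
#' @param description Output of [describe_herd()].
#' @return A tibble with a `statistic` column.
#' @export
describe_panel <- function(description) {
  description |>
    tidyr::pivot_longer(-"variable", names_to = "statistic") |>
    tidyr::pivot_wider(names_from = "variable") |>
    dplyr::mutate(statistic = factor(.data$statistic,
                                     levels = unique(.data$statistic))) |>
    dplyr::arrange(.data$statistic) |>
    dplyr::mutate(statistic = as.character(.data$statistic))
}

#' Default age-group bin edges
#'
#' Contiguous half-open age bins (months) used for the grouped
#' descriptive panel: `[22.3, 42.4), [42.4, 62.4), [62.4, 82.4),
#' [82.4, 102.4), [102.4, 110]` — the last bin closed.
#'
#' @return Numeric vector of bin edges.
#' @export
herd_age_bins <- function() c(22.3, 42.4, 62.4, 82.4, 102.4, 110)

#' Grouped descriptive panel
#'
#' Splits the table into bins of `group_var` by `bin_edges` — half-open
#' `[a, b)` except the last bin, which is closed — and applies
#' [summary_stats()] per bin and variable. Bins with a single row report
#' dispersion-dependent statistics as `NA` markers.
#'
#' @param table A data frame of herd records.
#' @param group_var Column to bin on (character scalar).
#' @param bin_edges Strictly increasing numeric edges (length `>= 2`).
#' @param vars Columns to summarise; default all numeric columns except
#'   `group_var`.
#' @return A tibble with `variable`, `bin` and the statistic columns.
#' @export
#' @examples
#' herd <- generate_herd(generator_config(n_records = 500, seed = 1))
#' describe_by_group(herd, "age_months")
describe_by_group <- function(table, group_var, bin_edges = herd_age_bins(),
                              vars = NULL) {
  table <- as_tibble(table)
  if (!group_var %in% names(table)) {
    abort(sprintf("describe_by_group: column '%s' not found", group_var))
  }
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    abort("bin_edges must be strictly increasing with length >= 2")
  }
  g <- table[[group_var]]
  outside <- g < bin_edges[1] | g > bin_edges[length(bin_edges)]
  if (any(outside)) {
    abort(paste0(
      "describe_by_group: values of ", group_var, " outside all bins: ",
      paste(utils::head(unique(g[outside]), 5), collapse = ", ")
    ))
  }
  nb <- length(bin_edges) - 1L
  idx <- findInterval(g, bin_edges, rightmost.closed = TRUE)
  labels <- sprintf("[%g, %g%s", bin_edges[-length(bin_edges)],
                    bin_edges[-1], c(rep(")", nb - 1L), "]"))
  if (is.null(vars)) {
    vars <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], group_var)
  }
  purrr::map_dfr(seq_len(nb), function(b) {
    rows <- table[idx == b, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    describe_herd(rows, vars = vars, allow_degenerate = TRUE) |>
      dplyr::mutate(bin = labels[b], .after = "variable")
  })
}
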