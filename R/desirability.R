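#' One-sided Derringer-Suich desirability
#'
#' Maps a predicted response to `[0, 1]`. For a `"maximize"` goal the
#' desirability is 0 at or below `anchor_low`, 1 at or above
#' `anchor_high`, and `((yhat - anchor_low)/(anchor_high - anchor_low))^weight`
#' between; a `"minimize"` goal is the mirror image. The map is
#' continuous and monotone in `yhat`.
#'
#' @param yhat Predicted response (vectorised).
#' @param goal `"maximize"` or `"minimize"`.
#' @param anchor_low,anchor_high Desirability anchors
#'   (`anchor_low < anchor_high`), in response units.
#' @param weight Power of the ramp (`> 0`, default 1 = linear).
#' @return Numeric vector of desirabilities in `[0, 1]`.
#' @export
#' @examples
#' desirability(0.5, "maximize", 0, 1)            # 0.5
#' desirability(0.5, "maximize", 0, 1, weight = 2) # 0.25
desirability <- function(yhat, goal = c("maximize", "minimize"),
                         anchor_low, anchor_high, weight = 1) {
  goal <- match.arg(goal)
  stopifnot(anchor_low < anchor_high, weight > 0)
  u <- (yhat - anchor_low) / (anchor_high - anchor_low)
  u <- pmin(pmax(u, 0), 1)
  if (goal == "minimize") u <- 1 - u
  u^weight
}

#' Importance-weighted composite desirability
#'
#' The weighted geometric mean `D = (prod d_i^I_i)^(1/sum I_i)`:
#' `D` lies between the smallest and largest individual desirability, is
#' zero exactly when some `d_i` is zero, and equals `c` when all
#' `d_i = c`.
#'
#' @param d Vector of individual desirabilities in `[0, 1]`.
#' @param importance Positive importance weights, recycled to `length(d)`.
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' composite_desirability(c(0.25, 1)) # 0.5
composite_desirability <- function(d, importance = 1) {
  importance <- rep_len(importance, length(d))
  stopifnot(all(importance > 0), all(d >= 0), all(d <= 1))
  if (any(d == 0)) return(0)
  exp(sum(importance * log(d)) / sum(importance))
}

#' Declare one optimization objective
#'
#' Binds a fitted (or fixed) response model to a goal and its
#' desirability anchors.
#'
#' @param model A `herd_lm`.
#' @param goal `"maximize"` or `"minimize"`.
#' @param anchor_low,anchor_high Desirability anchors
#'   (`anchor_low < anchor_high`).
#' @param weight Desirability ramp power (default 1).
#' @param importance Relative importance in the composite (default 1).
#' @param name Objective label; defaults to the model's response name.
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(model, goal = c("maximize", "minimize"),
                           anchor_low, anchor_high,
                           weight = 1, importance = 1, name = NULL) {
  goal <- match.arg(goal)
  stopifnot(inherits(model, "herd_lm"), anchor_low < anchor_high,
            weight > 0, importance > 0)
  structure(
    list(model = model, goal = goal,
         anchor_low = anchor_low, anchor_high = anchor_high,
         weight = weight, importance = importance,
         name = name %||% model$response_name),
    class = "objective_spec"
  )
}
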