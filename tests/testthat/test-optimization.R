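test_that("one-sided desirability ramps, saturates and mirrors", {
  expect_equal(desirability(1, "maximize", 0, 1), 1)
  expect_equal(desirability(-0.5, "maximize", 0, 1), 0)
  expect_equal(desirability(0.5, "maximize", 0, 1), 0.5)
  expect_equal(desirability(0.5, "maximize", 0, 1, weight = 2), 0.25)
  expect_equal(desirability(0.5, "minimize", 0, 1), 0.5)
  expect_equal(desirability(0, "minimize", 0, 1), 1)
  # monotone and continuous across the anchors
  y <- seq(-1, 2, by = 0.01)
  d <- desirability(y, "maximize", 0, 1, weight = 2)
  expect_true(all(diff(d) >= 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("composite desirability is the importance-weighted geometric mean", {
  expect_equal(composite_desirability(c(0, 0.9)), 0)
  expect_equal(composite_desirability(c(0.3, 0.3, 0.3)), 0.3)
  expect_equal(composite_desirability(c(0.25, 1)), 0.5)
  expect_equal(composite_desirability(c(0.25, 1), importance = c(2, 1)),
               (0.25^2)^(1 / 3))
})

test_that("evaluate_settings reproduces the reference optimum prediction", {
  pr <- herd_problem()
  ev <- evaluate_settings(pr, published_optimum(20))
  expect_equal(ev$responses$prediction[ev$responses$objective == "milk_yield"],
               61.15246, tolerance = 1e-6)
  d <- ev$responses$desirability
  expect_gte(ev$composite, min(d))
  expect_lte(ev$composite, max(d))
  expect_error(evaluate_settings(pr, published_optimum(200)),
               "temperature_c")
})

test_that("a monotone linear objective is optimized exactly at the box vertex", {
  m <- fixed_herd_model(c("(Intercept)" = 0, a = 1, b = -2, c = 0.5))
  box_l <- setNames(c(-1, 0, 2), c("a", "b", "c"))
  box_u <- setNames(c(3, 1, 5), c("a", "b", "c"))
  pr <- optimization_problem(objective_spec(m, "maximize", 0, 10),
                             box_l, box_u)
  res <- optimize_settings(pr, n_starts = 5, seed = 2)
  expect_identical(unname(res$settings), c(3, 0, 5))
  # minimize goal lands on the opposite vertex
  pr2 <- optimization_problem(objective_spec(m, "minimize", -10, 10),
                              box_l, box_u)
  res2 <- optimize_settings(pr2, n_starts = 5, seed = 2)
  expect_identical(unname(res2$settings), c(-1, 1, 2))
})

test_that("optimizer agrees with the grid oracle on random bi-objective problems", {
  for (s in 1:5) {
    pr <- random_problem(s)
    res <- optimize_settings(pr, n_starts = 8, seed = s)
    gr <- grid_oracle(pr, 21)
    expect_lt(abs(res$composite - gr$composite), 1e-3, label = paste("seed", s))
    expect_true(all(res$settings >= pr$lower & res$settings <= pr$upper))
  }
})

test_that("grid oracle enumerates vertices at 2 points per dimension and refines monotonically", {
  pr <- random_problem(17)
  g2 <- grid_oracle(pr, 2)
  expect_equal(g2$diagnostics$grid_points, 2^3)
  # the 2-point grid optimum is a vertex
  at_bound <- res <- abs(g2$settings - pr$lower) < 1e-12 |
    abs(g2$settings - pr$upper) < 1e-12
  expect_true(all(at_bound))
  # nested grids: 41 contains 21's points, so D cannot decrease
  expect_gte(grid_oracle(pr, 41)$composite, grid_oracle(pr, 21)$composite - 1e-12)
  expect_error(grid_oracle(herd_problem(), 50), "too large")
})

test_that("factor order does not change the optimum desirability", {
  pr <- random_problem(3)
  perm <- c("c", "a", "b")
  pr_perm <- optimization_problem(pr$objectives, pr$lower[perm],
                                  pr$upper[perm])
  r1 <- optimize_settings(pr, n_starts = 8, seed = 1)
  r2 <- optimize_settings(pr_perm, n_starts = 8, seed = 1)
  expect_lt(abs(r1$composite - r2$composite), 1e-9)
})

test_that("the herd problem dominates the reference settings and respects integrality", {
  pr <- herd_problem()
  res <- optimize_settings(pr, n_starts = 20, seed = 1)
  ref <- evaluate_settings(pr, published_optimum(20))
  expect_gte(res$composite, ref$composite)
  expect_identical(res$settings[["lactation_number"]],
                   round(res$settings[["lactation_number"]]))
  expect_true(all(res$settings >= pr$lower & res$settings <= pr$upper))
  expect_true(res$diagnostics$converged)
  # per-objective interval columns present
  expect_true(all(c("se_fit", "ci_low", "pi_high") %in% names(tidy(res))))
})

test_that("optimization is deterministic given the seed", {
  pr <- herd_problem()
  r1 <- optimize_settings(pr, n_starts = 10, seed = 4)
  r2 <- optimize_settings(pr, n_starts = 10, seed = 4)
  expect_identical(r1$settings, r2$settings)
  expect_identical(r1$composite, r2$composite)
})

test_that("unattainable anchors yield a flagged zero-desirability result", {
  m <- fixed_herd_model(c("(Intercept)" = 0, a = 1))
  pr <- optimization_problem(
    objective_spec(m, "maximize", 100, 200),   # response never reaches 100
    c(a = 0), c(a = 1))
  res <- optimize_settings(pr, n_starts = 3, seed = 1)
  expect_equal(res$composite, 0)
  expect_false(res$diagnostics$converged)
})
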