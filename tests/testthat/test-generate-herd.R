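test_that("the same config yields a bit-identical table", {
  cfg <- generator_config(n_records = 300, seed = 7)
  expect_identical(generate_herd(cfg), generate_herd(cfg))
})

test_that("all generated factor values respect their bounds", {
  herd <- small_herd()
  for (sp in herd_factor_specs()) {
    x <- herd[[sp$name]]
    expect_true(all(x >= sp$lower & x <= sp$upper), label = sp$name)
  }
  expect_false(anyNA(herd))
})

test_that("a degenerate model produces a constant response", {
  specs <- herd_factor_specs()
  b0 <- setNames(c(109.87, rep(0, 6)),
                 c("(Intercept)", herd_columns("factors")))
  cfg <- generator_config(
    factor_specs = specs, milk_coefficients = b0, dm_coefficients = b0,
    milk_target_variance = 1e-12, dm_target_variance = 1e-12,
    milk_target_mean = NA, dm_target_mean = NA,
    n_records = 100, seed = 3
  )
  herd <- generate_herd(cfg)
  expect_true(all(abs(herd$milk_yield - 109.87) < 1e-4))
})

test_that("implied_residual_sd decomposes the target variance", {
  # model explains nothing
  expect_equal(implied_residual_sd(c(5, 0), data.frame(x = rnorm(50)), 4), 2)
  # oracle: recompute the linear-predictor variance directly
  herd <- small_herd()
  b <- milk_yield_coefficients()
  factors <- herd[herd_columns("factors")]
  linpred <- as.matrix(factors) %*% b[-1]
  expected <- sqrt(80.979 - var(as.vector(linpred)))
  expect_equal(implied_residual_sd(b, factors, 80.979), expected,
               tolerance = 1e-12)
  # floor keeps the result valid when the predictor over-explains
  tiny <- implied_residual_sd(b, factors, 1e-3)
  expect_equal(tiny, sqrt(1e-6 * 1e-3))
})

test_that("response marginal variance matches its calibration target", {
  herd <- small_herd()
  expect_lt(abs(var(herd$milk_yield) - 80.979) / 80.979, 0.10)
  expect_lt(abs(var(herd$dm_intake) - 7.705) / 7.705, 0.10)
})

test_that("independent factors are uncorrelated and a copula induces dependence", {
  herd <- small_herd()
  n <- nrow(herd)
  cors <- cor(herd[herd_columns("factors")])
  expect_lt(max(abs(cors[upper.tri(cors)])), 4 / sqrt(n))

  R <- diag(6)
  R[1, 6] <- R[6, 1] <- 0.5
  herd_c <- generate_herd(generator_config(n_records = 4000, seed = 5,
                                           correlation = R))
  expect_gt(cor(herd_c$tmr_dm_pct, herd_c$temperature_c), 0.35)
  # marginals survive the copula
  expect_lt(abs(mean(herd_c$temperature_c) - 22.781), 0.5)
})

test_that("invalid correlation matrices are rejected", {
  R <- diag(6); R[1, 2] <- 0.5       # asymmetric
  expect_error(generator_config(correlation = R), "symmetric")
  R2 <- matrix(0.99, 6, 6); diag(R2) <- 1
  R2[1, 2] <- R2[2, 1] <- -0.99      # not positive definite
  expect_error(generator_config(correlation = R2), "positive definite")
})
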