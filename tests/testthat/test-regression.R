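test_that("build_design lays out intercept, main effects and interactions", {
  tbl <- tibble::tibble(y = 1:3, a = 4:6, b = 7:9)
  d <- build_design(tbl, "y", c("a", "b"))
  expect_equal(dim(d$design), c(3, 3))
  expect_equal(unname(d$design[, 1]), rep(1, 3))
  expect_equal(colnames(d$design), c("(Intercept)", "a", "b"))

  di <- build_design(tbl, "y", c("a", "b"), interactions = TRUE)
  expect_equal(ncol(di$design), 4)
  expect_equal(unname(di$design[, "a:b"]), tbl$a * tbl$b)

  expect_error(build_design(tbl, "y", c("a", "zz")), "zz")
  expect_error(build_design(tbl[0, ], "y", "a"), "zero rows")
})

test_that("fit_ols interpolates exact linear data", {
  tbl <- tibble::tibble(x = 1:10, y = 2 + 3 * (1:10))
  fit <- fit_ols(build_design(tbl, "y", "x"))
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_lt(fit$sigma2, 1e-20)
  expect_equal(fit$r_squared, 1)
})

test_that("fit_ols matches the explicit normal-equations solution", {
  # oracle: brute-force (X'X)^{-1} X'y on a small hand dataset
  tbl <- tibble::tibble(x1 = c(1, 2, 3, 4, 5), x2 = c(2, 1, 4, 3, 6),
                        y = c(3.1, 4.0, 8.2, 7.9, 12.5))
  fit <- fit_ols(build_design(tbl, "y", c("x1", "x2")))
  X <- cbind(1, tbl$x1, tbl$x2)
  beta <- solve(t(X) %*% X) %*% t(X) %*% tbl$y
  expect_equal(unname(fit$coefficients), as.vector(beta), tolerance = 1e-10)
  # residuals orthogonal to every design column
  res <- tbl$y - X %*% beta
  expect_lt(max(abs(t(X) %*% res)) / sum(abs(tbl$y)), 1e-8)
  # covariance and intervals agree with the standard implementation
  lmfit <- lm(y ~ x1 + x2, tbl)
  expect_equal(unname(fit$vcov), unname(vcov(lmfit)), tolerance = 1e-10)
})

test_that("a constant column is flagged as rank deficient by name", {
  tbl <- tibble::tibble(x = 1:8, const = 1, y = rnorm(8))
  expect_error(fit_ols(build_design(tbl, "y", c("x", "const"))),
               "const", class = "herdopt_rank_error")
})

test_that("slope recovery: simulated herds give estimates near the generating equation", {
  herd <- small_herd()
  fit <- fit_herd_model(herd, "milk_yield")
  td <- tidy(fit)
  tmr <- td[td$term == "tmr_dm_pct", ]
  expect_lt(abs(tmr$estimate - (-0.9148)), 2.5 * tmr$std.error)
})

test_that("adjusted SS equals full-vs-reduced RSS differences and F equals t squared", {
  herd <- small_herd()
  fit <- fit_herd_model(herd, "milk_yield")
  an <- anova_adjusted(fit)
  td <- tidy(fit)
  # oracle: refit each reduced model with lm and difference the RSS
  full <- lm(milk_yield ~ tmr_dm_pct + lactation_number + lactation_day +
               gestation_day + age_months + temperature_c, herd)
  for (term in herd_columns("factors")) {
    reduced <- update(full, stats::as.formula(paste(". ~ . -", term)))
    expect_equal(an$adj_ss[an$term == term],
                 sum(resid(reduced)^2) - sum(resid(full)^2),
                 tolerance = 1e-8, label = term)
  }
  expect_equal(an$f_value[match(td$term[-1], an$term)],
               td$statistic[-1]^2, tolerance = 1e-10)
  expect_true(all(an$adj_ss >= 0))
  expect_equal(an$adj_ms, an$adj_ss / an$df)
})

test_that("single-term adjusted SS is the regression sum of squares", {
  tbl <- tibble::tibble(x = rnorm(50), y = 1 + 2 * x + rnorm(50))
  fit <- fit_ols(build_design(tbl, "y", "x"))
  an <- anova_adjusted(fit)
  tss <- sum((tbl$y - mean(tbl$y))^2)
  expect_equal(an$adj_ss[an$term == "x"], tss - fit$rss, tolerance = 1e-10)
})

test_that("orthogonal designs make adjusted and sequential SS coincide", {
  x1 <- rep(c(-1, 1), each = 8)
  x2 <- rep(c(-1, 1), times = 8)
  tbl <- tibble::tibble(x1 = x1, x2 = x2,
                        y = withr::with_seed(3, 1 + x1 - 2 * x2 + rnorm(16)))
  fit <- fit_ols(build_design(tbl, "y", c("x1", "x2")))
  an <- anova_adjusted(fit)
  seq_an <- anova(lm(y ~ x1 + x2, tbl))
  expect_equal(an$adj_ss[1:2], seq_an$`Sum Sq`[1:2], tolerance = 1e-10)
})

test_that("p-value display floors at 0.001 while stored values stay exact", {
  herd <- small_herd()
  an <- anova_adjusted(fit_herd_model(herd, "milk_yield"))
  expect_true(any(an$p_value < 0.001, na.rm = TRUE))
  shown <- format_anova(an)
  expect_true(all(shown$p_value[!is.na(shown$p_value)] >= "0.001"))
})

test_that("standardized effects rank like ANOVA F and use the t cutoff", {
  herd <- small_herd()
  fit <- fit_herd_model(herd, "milk_yield")
  eff <- standardized_effects(fit)
  an <- anova_adjusted(fit)
  an_terms <- an$term[order(-an$f_value)][seq_len(nrow(eff))]
  expect_equal(eff$term, an_terms)          # t^2 = F for 1-df terms
  expect_equal(eff$t_abs^2,
               an$f_value[match(eff$term, an$term)], tolerance = 1e-10)
  expect_lt(abs(eff$critical[1] - qnorm(0.975)), 0.01)  # large-df limit
})

test_that("predict_point reproduces the textbook interval formulas", {
  herd <- small_herd()
  fit <- fit_herd_model(herd, "milk_yield")
  pt <- published_optimum()
  pp <- predict_point(fit, pt)
  # oracle: lm's fit/se/PI at the same point
  lmfit <- lm(milk_yield ~ tmr_dm_pct + lactation_number + lactation_day +
                gestation_day + age_months + temperature_c, herd)
  nd <- as.data.frame(as.list(pt))
  pr_c <- predict(lmfit, nd, interval = "confidence", se.fit = TRUE)
  pr_p <- predict(lmfit, nd, interval = "prediction")
  expect_equal(pp$fit, unname(pr_c$fit[1, "fit"]), tolerance = 1e-10)
  expect_equal(pp$se_fit, unname(pr_c$se.fit), tolerance = 1e-10)
  expect_equal(c(pp$ci_low, pp$ci_high),
               unname(pr_c$fit[1, c("lwr", "upr")]), tolerance = 1e-10)
  expect_equal(c(pp$pi_low, pp$pi_high),
               unname(pr_p[1, c("lwr", "upr")]), tolerance = 1e-10)
  # CI strictly inside PI when s^2 > 0
  expect_lt(pp$pi_low, pp$ci_low)
  expect_gt(pp$pi_high, pp$ci_high)
  expect_error(predict_point(fit, pt[-1]), "tmr_dm_pct")
})

test_that("the SE of the mean prediction at the factor-mean point is s/sqrt(n)-like", {
  herd <- small_herd()
  fit <- fit_herd_model(herd, "milk_yield")
  centre <- vapply(herd[herd_columns("factors")], mean, 0)
  pp <- predict_point(fit, centre)
  expect_lt(abs(pp$se_fit - sqrt(fit$sigma2 / fit$nobs)) /
              sqrt(fit$sigma2 / fit$nobs), 0.05)
})

test_that("a fixed model evaluates the reference milk equation exactly", {
  m <- fixed_herd_model(milk_yield_coefficients(), response_name = "milk_yield")
  pp <- predict_point(m, published_optimum(20))
  expect_equal(pp$fit, 61.15246, tolerance = 1e-6)
  expect_equal(pp$se_fit, 0)
  expect_equal(pp$ci_low, pp$pi_low)
  # intercept-only evaluation
  m0 <- fixed_herd_model(c("(Intercept)" = 5))
  expect_equal(predict_point(m0, c(x = 1))$fit, 5)
})

test_that("equation text renders signs and terms in order", {
  m <- fixed_herd_model(milk_yield_coefficients(), response_name = "milk_yield")
  txt <- equation_text(m)
  expect_match(txt, "^milk_yield = 109.9 - 0.9148 tmr_dm_pct \\+ 3.753 lactation_number")
})
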