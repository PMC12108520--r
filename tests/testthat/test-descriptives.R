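test_that("quartiles follow the (n+1)p interpolation rule", {
  # oracle: hand interpolation at positions (n+1)p clamped to [1, n]
  np_rule <- function(x, p) {
    x <- sort(x)
    h <- pmin(pmax((length(x) + 1) * p, 1), length(x))
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  expect_equal(unname(quartiles(1:5)), c(1.5, 3, 4.5))
  expect_equal(unname(quartiles(1:3)), c(1, 2, 3))
  expect_equal(unname(quartiles(rep(3, 4))), c(3, 3, 3))
  for (s in 1:5) {
    x <- withr::with_seed(s, rnorm(25 + s))
    expect_equal(unname(quartiles(x)), np_rule(x, c(0.25, 0.5, 0.75)))
  }
  expect_error(quartiles(numeric(0)), "finite")
})

test_that("summary_stats reports the full panel with consistent fields", {
  st <- summary_stats(c(-2, -1, 0, 1, 2))
  expect_equal(st$skewness, 0)
  expect_equal(st$variance, st$sd^2)
  expect_equal(st$se_mean, st$sd / sqrt(st$n))
  expect_equal(summary_stats(c(0, 0, 0, 1))$mean, 0.25)
  expect_true(st$minimum <= st$q1 && st$q1 <= st$median &&
                st$median <= st$q3 && st$q3 <= st$maximum)
  # large-sample normal kurtosis tends to 0 under the adjusted convention
  x <- withr::with_seed(2, rnorm(1e5))
  expect_lt(abs(summary_stats(x)$kurtosis), 0.1)
  expect_error(summary_stats(5), "n < 2")
})

test_that("summary_stats is permutation invariant and affine equivariant", {
  x <- withr::with_seed(9, rgamma(200, 2))
  expect_equal(summary_stats(x), summary_stats(sample(x)))
  a <- -2.5; b <- 7
  s1 <- summary_stats(x)
  s2 <- summary_stats(a * x + b)
  expect_equal(s2$mean, a * s1$mean + b)
  expect_equal(s2$median, a * s1$median + b)
  expect_equal(s2$q1, a * s1$q3 + b)   # negative scale flips quartiles
  expect_equal(s2$sd, abs(a) * s1$sd)
  expect_equal(s2$skewness, sign(a) * s1$skewness)
})

test_that("grouped summaries partition the data and match the global panel", {
  herd <- small_herd()
  # one bin covering everything reproduces the global summary
  edges <- range(herd$age_months) + c(-1, 1)
  grouped <- describe_by_group(herd, "age_months", edges)
  global <- describe_herd(herd, vars = setdiff(
    names(herd)[vapply(herd, is.numeric, TRUE)], "age_months"))
  expect_equal(grouped[names(global)], global)

  # bins partition: concatenated n, min and max reproduce the global table
  grouped5 <- describe_by_group(herd, "age_months", herd_age_bins())
  by_var <- dplyr::summarise(
    dplyr::group_by(grouped5, .data$variable),
    n = sum(n), minimum = min(minimum), maximum = max(maximum))
  milk <- by_var[by_var$variable == "milk_yield", ]
  expect_equal(milk$n, nrow(herd))
  expect_equal(milk$minimum, min(herd$milk_yield))
  expect_equal(milk$maximum, max(herd$milk_yield))
})

test_that("a single-row bin reports dispersion as NA markers, not zero", {
  tbl <- tibble::tibble(age_months = c(30, 30, 90),
                        milk_yield = c(50, 52, 47))
  out <- describe_by_group(tbl, "age_months", c(20, 60, 100))
  lone <- out[out$bin == "[60, 100]", ]
  expect_equal(lone$mean, 47)
  expect_true(is.na(lone$sd))
  expect_true(is.na(lone$skewness))
})

test_that("rows outside all bins raise an error listing the values", {
  tbl <- tibble::tibble(age_months = c(30, 150), milk_yield = c(50, 52))
  expect_error(describe_by_group(tbl, "age_months", c(20, 100)), "150")
})

test_that("two equal-width bins on uniform data split the counts evenly", {
  # oracle: bin count is Binomial(n, 1/2)
  n <- 2000
  tbl <- tibble::tibble(age_months = withr::with_seed(4, runif(n, 0, 10)),
                        milk_yield = 1:n)
  out <- describe_by_group(tbl, "age_months", c(0, 5, 10), vars = "milk_yield")
  expect_lt(abs(out$n[1] - n / 2), 3 * sqrt(n * 0.25))
})

test_that("describe_panel pivots to one row per statistic", {
  herd <- small_herd()
  panel <- describe_panel(describe_herd(herd))
  expect_equal(panel$statistic[1:2], c("n", "mean"))
  expect_true(all(herd_columns() %in% names(panel)))
})
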