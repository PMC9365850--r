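series_from <- function(years, values) data.frame(year = years, value = values)

test_that("the zero-knot basis reproduces cubics on the fitted (log) scale exactly", {
  years <- 1900:1950
  tt <- (years - 1900) / 50
  s <- 1 + 2 * tt - 3 * tt^2 + 1.5 * tt^3   # cubic on the log scale
  f <- fit_spline(series_from(years, exp(s)), 0, offset_c = 0)
  expect_lt(max(abs(f$residuals_log)), 1e-8)
  curve <- evaluate_spline(f, years, order = 0, scale = "log")
  expect_equal(curve$value, s, tolerance = 1e-8)
})

test_that("basis rows sum to one and columns count p = k + 4", {
  years <- seq(1900, 2019, by = 0.5)
  for (k in c(0, 3, 10)) {
    B <- cubic_basis(years, k, c(1900, 2019))
    expect_equal(ncol(B), k + 4)
    expect_equal(rowSums(B), rep(1, length(years)), tolerance = 1e-12)
  }
})

test_that("basis derivatives match centred finite differences", {
  years <- seq(1905, 2015, by = 5)
  h <- 1e-5
  for (ord in 1:2) {
    lower <- cubic_basis(years - h, ord - 1, c(1900, 2019))
    upper <- cubic_basis(years + h, ord - 1, c(1900, 2019))
    fd <- (upper - lower) / (2 * h)
    an <- cubic_basis(years, ord - 1, c(1900, 2019), order = 1)
    expect_lt(max(abs(fd - an)), 1e-4)
  }
})

test_that("over-parameterised fits and tiny series are errors", {
  years <- 1900:1911
  y <- runif(12, 1, 2)
  expect_error(fit_spline(series_from(years, y), 10), "over-parameterized")
  expect_error(fit_spline(series_from(1900:1905, runif(6, 1, 2)), 0),
               "at least 8")
})

test_that("a constant series fits a flat curve with zero derivatives", {
  f <- fit_spline(series_from(1900:1999, rep(5, 100)), 2, offset_c = 0.5)
  expect_equal(unique(round(f$fitted_log, 10)), round(log(5.5), 10))
  g <- evaluate_spline(f, 1900:1999, order = 1, scale = "log")
  expect_lt(max(abs(g$value)), 1e-10)
  gn <- evaluate_spline(f, 1900:1999, order = 1, scale = "natural")
  expect_lt(max(abs(gn$value)), 1e-8)
  cn <- evaluate_spline(f, 1950, order = 2, scale = "natural")
  expect_lt(abs(cn$value), 1e-8)
})

test_that("per-regime sigma recovers known heteroscedastic scatter", {
  set.seed(42)
  years <- 1900:2019  # n = 120
  s_true <- 2 + 0.01 * (years - 1900)
  sd_true <- ifelse(years <= 1985, 0.1, 0.5)
  y <- exp(s_true + rnorm(120, 0, sd_true))
  f <- fit_spline(series_from(years, y), 2, offset_c = 0,
                  variance_changepoint = 1985)
  expect_length(f$sigma, 2)
  expect_lt(abs(f$sigma[[1]] - 0.1) / 0.1, 0.2)
  expect_lt(abs(f$sigma[[2]] - 0.5) / 0.5, 0.2)
})

test_that("GCV selection matches an independent grid and is deterministic", {
  set.seed(9)
  years <- 1900:1979
  y <- exp(1 + 0.02 * (years - 1900) + rnorm(80, 0, 0.2))
  sel1 <- select_knots(series_from(years, y), 0, 8, offset_c = 0)
  sel2 <- select_knots(series_from(years, y), 0, 8, offset_c = 0)
  expect_identical(sel1$gcv_table, sel2$gcv_table)
  oracle <- oracle_gcv_grid(series_from(years, y), 0:8, offset_c = 0)
  expect_equal(sel1$gcv_table$gcv, oracle, tolerance = 1e-8)
  expect_equal(sel1$best_k, (0:8)[which.min(oracle)])
})

test_that("smooth data select few knots; a sharp bump demands more", {
  set.seed(10)
  years <- 1900:2019
  tt <- (years - 1900) / 119
  smooth_y <- exp(1 + 2 * tt^3 + rnorm(120, 0, 0.02))
  sel <- select_knots(series_from(years, smooth_y), 0, 6, offset_c = 0)
  # the cubic is exactly representable at k = 0, so the zero-knot fit is
  # already at noise level: its GCV is within a whisker of the minimum and
  # any extra knots buy no real fit improvement
  expect_lte(sel$gcv_table$gcv[1], 1.1 * min(sel$gcv_table$gcv))
  f0 <- fit_spline(series_from(years, smooth_y), 0, offset_c = 0)
  expect_lt(sqrt(f0$rss / 120), 0.03)  # residual sd at the noise level
  bump_y <- exp(1 + 3 * exp(-((years - 1960) / 5)^2) + rnorm(120, 0, 0.05))
  sel_b <- select_knots(series_from(years, bump_y), 0, 12, offset_c = 0)
  expect_gt(sel_b$best_k, 0)
})

test_that("natural-scale derivatives match finite differences of the curve", {
  set.seed(12)
  years <- 1900:2019
  y <- exp(1 + 0.03 * (years - 1900) + rnorm(120, 0, 0.3))
  f <- fit_spline(series_from(years, y), 5)
  xs <- seq(1905, 2015, by = 2.5)
  h <- 1e-5
  c0 <- function(x) evaluate_spline(f, x, 0, "natural")$value
  c1 <- function(x) evaluate_spline(f, x, 1, "natural")$value
  fd1 <- (c0(xs + h) - c0(xs - h)) / (2 * h)
  an1 <- c1(xs)
  expect_lt(max(abs(fd1 - an1) / pmax(abs(an1), 1)), 1e-4)
  fd2 <- (c1(xs + h) - c1(xs - h)) / (2 * h)
  an2 <- evaluate_spline(f, xs, 2, "natural")$value
  expect_lt(max(abs(fd2 - an2) / pmax(abs(an2), 1)), 1e-4)
})

test_that("fitting exponential growth recovers the log slope mid-window", {
  set.seed(13)
  years <- 1900:2019
  y <- exp(0.5 + 0.04 * (years - 1900) + rnorm(120, 0, 0.15))
  f <- fit_spline(series_from(years, y), 3, offset_c = 0)
  mid <- 1930:1990
  g <- evaluate_spline(f, mid, 1, "log")$value
  expect_lt(max(abs(g - 0.04) / 0.04), 0.10)
})

test_that("log-scale fits are shift equivariant (linear smoother)", {
  set.seed(14)
  years <- 1900:1999
  y <- exp(1 + rnorm(100, 0, 0.2))
  c0 <- 0.5
  f1 <- fit_spline(series_from(years, y), 4, offset_c = c0)
  y2 <- 2 * (y + c0) - c0  # (y2 + c0) = 2 (y + c0)
  f2 <- fit_spline(series_from(years, y2), 4, offset_c = c0)
  expect_equal(f2$fitted_log, f1$fitted_log + log(2), tolerance = 1e-10)
})

test_that("the gradient integrates back to the curve difference", {
  set.seed(15)
  years <- 1900:2019
  y <- exp(1 + 0.02 * (years - 1900) + rnorm(120, 0, 0.2))
  f <- fit_spline(series_from(years, y), 6)
  xs <- seq(1900, 2019, by = 0.01)
  g <- evaluate_spline(f, xs, 1, "log")$value
  integral <- sum((g[-1] + g[-length(g)]) / 2 * diff(xs))
  ends <- evaluate_spline(f, c(1900, 2019), 0, "log")$value
  expect_equal(integral, ends[2] - ends[1], tolerance = 1e-3 * abs(ends[2] - ends[1]))
})

test_that("evaluation outside the fitted window refuses to extrapolate", {
  f <- fit_spline(series_from(1900:1999, rep(5, 100)), 0)
  expect_error(evaluate_spline(f, 2005, 0), "extrapolation")
})
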