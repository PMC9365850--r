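flat_series <- function(n = 100, value = 5, start = 1900) {
  data.frame(year = seq(start, start + n - 1), value = rep(value, n))
}

test_that("config validation enforces the documented ranges", {
  expect_error(timeline_config(n_bootstrap = 50), "n_bootstrap")
  expect_error(timeline_config(conf = 1.2))
  expect_error(timeline_config(min_run = 0))
  cfg <- timeline_config(seed = 3)
  expect_equal(cfg$n_bootstrap, 1000L)
  expect_equal(cfg$conf, 0.95)
  expect_equal(cfg$min_run, 5L)
  expect_false(cfg$refit_knots)
})

test_that("a sigma = 0 fit collapses the bands onto the estimates, with a warning", {
  f <- fit_spline(flat_series(), 0, offset_c = 0.5)
  expect_warning(b <- bootstrap_bands(f, timeline_config(seed = 1, n_bootstrap = 100)),
                 "collapse")
  expect_equal(b$low, b$estimate, tolerance = 1e-10)
  expect_equal(b$high, b$estimate, tolerance = 1e-10)
})

test_that("bands are bit-identical across reruns with the same seed", {
  set.seed(20)
  s <- flat_series()
  s$value <- exp(log(10) + rnorm(100, 0, 0.3))
  f <- fit_spline(s, 3)
  b1 <- bootstrap_bands(f, timeline_config(seed = 77, n_bootstrap = 150))
  b2 <- bootstrap_bands(f, timeline_config(seed = 77, n_bootstrap = 150))
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  b3 <- bootstrap_bands(f, timeline_config(seed = 78, n_bootstrap = 150))
  expect_false(identical(b1$low, b3$low))
})

test_that("99% bands contain 95% bands pointwise", {
  set.seed(21)
  s <- flat_series(120)
  s$value <- exp(1 + 0.02 * (1:120) + rnorm(120, 0, 0.25))
  f <- fit_spline(s, 4)
  b95 <- bootstrap_bands(f, timeline_config(seed = 5, conf = 0.95, n_bootstrap = 400))
  b99 <- bootstrap_bands(f, timeline_config(seed = 5, conf = 0.99, n_bootstrap = 400))
  expect_true(all(b99$low <= b95$low + 1e-12))
  expect_true(all(b99$high >= b95$high - 1e-12))
})

test_that("gradient sign flags agree between log and natural scales", {
  set.seed(22)
  s <- flat_series(120)
  s$value <- exp(0.5 + 0.03 * (1:120) + rnorm(120, 0, 0.3))
  f <- fit_spline(s, 3)
  bl <- bootstrap_bands(f, timeline_config(seed = 9, n_bootstrap = 300, scale = "log"))
  bn <- bootstrap_bands(f, timeline_config(seed = 9, n_bootstrap = 300, scale = "natural"))
  gl <- bl[bl$attribute == "gradient", ]
  gn <- bn[bn$attribute == "gradient", ]
  expect_equal(gl$significant, gn$significant)
  expect_equal(gl$sign, gn$sign)
})

make_bands <- function(years, low, high, attribute = "gradient") {
  structure(
    tibble::tibble(year = years, attribute = attribute,
                   estimate = (low + high) / 2, low = low, high = high,
                   significant = low > 0 | high < 0,
                   sign = ifelse(low > 0, "positive",
                                 ifelse(high < 0, "negative", "none"))),
    config = timeline_config(seed = 1), class = c("trend_bands", "tbl_df",
                                                  "tbl", "data.frame"))
}

test_that("significant periods are the maximal runs of >= min_run years", {
  years <- 1995:2010
  low <- rep(-0.2, 16); high <- rep(0.3, 16)
  low[years >= 2000 & years <= 2006] <- 0.1  # significant 2000-2006
  b <- make_bands(years, low, high)
  p <- significant_periods(b, 5)
  expect_equal(nrow(p), 1)
  expect_equal(p$start_year, 2000)
  expect_equal(p$end_year, 2006)
  expect_equal(p$sign, "positive")
  expect_equal(p$duration, 7)
})

test_that("runs of exactly 4 years and alternating patterns yield no period", {
  years <- 2000:2015
  low <- rep(-0.2, 16); high <- rep(0.3, 16)
  low[3:6] <- 0.1  # 4 consecutive years only
  expect_equal(nrow(significant_periods(make_bands(years, low, high), 5)), 0)
  low2 <- rep(-0.2, 16); high2 <- rep(0.3, 16)
  low2[seq(1, 16, by = 2)] <- 0.1  # alternate
  expect_equal(nrow(significant_periods(make_bands(years, low2, high2), 5)), 0)
})

test_that("period extraction matches an exhaustive run-length oracle", {
  set.seed(30)
  for (rep in 1:20) {
    n <- 40
    code <- sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(0.25, 0.4, 0.35))
    years <- 1980 + seq_len(n) - 1
    low <- ifelse(code == 1L, 0.1, ifelse(code == -1L, -0.5, -0.1))
    high <- ifelse(code == 1L, 0.5, ifelse(code == -1L, -0.1, 0.1))
    p <- significant_periods(make_bands(years, low, high), 5)
    runs <- oracle_runs(code, 5)
    expect_equal(nrow(p), length(runs))
    for (i in seq_along(runs)) {
      expect_equal(p$start_year[i], years[runs[[i]]["start"]])
      expect_equal(p$end_year[i], years[runs[[i]]["end"]])
      expect_equal(p$sign[i], if (runs[[i]]["sign"] > 0) "positive" else "negative")
    }
  }
})

test_that("reported periods are maximal: one more year breaks sign or significance", {
  set.seed(31)
  s <- flat_series(120)
  s$value <- exp(ifelse(1:120 < 60, 1, 1 + 0.06 * (1:120 - 60)) +
                   rnorm(120, 0, 0.2))
  res <- run_timeline(s, spline_options = list(k_max = 8),
                      config = timeline_config(seed = 41, n_bootstrap = 300))
  b <- res$bands
  for (i in seq_len(nrow(res$periods))) {
    p <- res$periods[i, ]
    sub <- b[b$attribute == p$attribute, ]
    before <- sub[sub$year == p$start_year - 1, ]
    after <- sub[sub$year == p$end_year + 1, ]
    if (nrow(before)) expect_false(before$significant && before$sign == p$sign)
    if (nrow(after)) expect_false(after$significant && after$sign == p$sign)
  }
})

test_that("the composed timeline run is reproducible and carries its audit", {
  set.seed(32)
  s <- flat_series(120)
  s$value <- exp(1 + 0.02 * (1:120) + rnorm(120, 0, 0.2))
  r1 <- run_timeline(s, spline_options = list(k_max = 6),
                     config = timeline_config(seed = 55, n_bootstrap = 200))
  r2 <- run_timeline(s, spline_options = list(k_max = 6),
                     config = timeline_config(seed = 55, n_bootstrap = 200))
  expect_identical(as.data.frame(r1$bands), as.data.frame(r2$bands))
  expect_identical(r1$periods, r2$periods)
  expect_equal(r1$audit$seed, 55L)
  expect_true(all(c("best_k", "gcv_table", "sigma") %in% names(r1$audit)))
  expect_equal(nrow(r1$audit$gcv_table), 7)
})

test_that("knot re-selection inside the bootstrap agrees with a per-replicate oracle", {
  set.seed(33)
  s <- flat_series(60)
  s$value <- exp(1 + rnorm(60, 0, 0.2))
  f <- fit_spline(s, 0)
  cfg <- timeline_config(seed = 66, n_bootstrap = 100, refit_knots = TRUE,
                         scale = "log")
  b <- bootstrap_bands(f, cfg, k_min = 0, k_max = 4)
  # oracle: redraw the same replicate noise and re-select k per replicate
  # through the public fit/select functions, then take the same quantiles
  n <- nrow(s)
  set.seed(cfg$seed)
  E <- matrix(rnorm(n * cfg$n_bootstrap), n, cfg$n_bootstrap) * f$sigma[[1]]
  eval_years <- s$year
  G <- sapply(seq_len(cfg$n_bootstrap), function(bb) {
    zb <- f$fitted_log + E[, bb]
    db <- data.frame(year = s$year, value = pmax(exp(zb) - f$offset_c, 0))
    sel <- select_knots(db, 0, 4, offset_c = f$offset_c)
    evaluate_spline(sel$fit, eval_years, 1, "log")$value
  })
  want_low <- apply(G, 1, quantile, probs = 0.025, type = 7, names = FALSE)
  want_high <- apply(G, 1, quantile, probs = 0.975, type = 7, names = FALSE)
  g <- b[b$attribute == "gradient", ]
  expect_equal(g$low, want_low, tolerance = 1e-9)
  expect_equal(g$high, want_high, tolerance = 1e-9)
})
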