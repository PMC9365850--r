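# Cubic regression splines with equidistant knots, fitted by least squares
# to log-transformed annual series, knot count chosen by GCV.

spline_knot_vector <- function(window, k) {
  a <- window[1]; b <- window[2]
  interior <- if (k > 0) a + seq_len(k) * (b - a) / (k + 1) else numeric(0)
  c(rep(a, 4), interior, rep(b, 4))
}

#' Cubic B-spline design matrix on equidistant knots
#'
#' Builds the cubic B-spline basis with `n_interior_knots` equidistant
#' interior knots spanning `window` (boundary knots at the window ends).
#' The basis has `p = n_interior_knots + 4` columns, spans all cubic
#' polynomials when `n_interior_knots = 0`, and any weighted sum of columns
#' is twice continuously differentiable.
#'
#' @param years evaluation points (at least 8 distinct values when building
#'   a design for fitting).
#' @param n_interior_knots number of equidistant interior knots (>= 0).
#' @param window numeric `c(start, end)`; defaults to `range(years)`.
#' @param order derivative order 0, 1, or 2 of the basis functions.
#' @return Matrix with one row per year, `p` columns; attributes `knots`
#'   (interior knots) and `window`.
#' @export
cubic_basis <- function(years, n_interior_knots, window = range(years),
                        order = 0) {
  stopifnot(n_interior_knots >= 0, order %in% 0:2)
  kn <- spline_knot_vector(window, n_interior_knots)
  B <- splines::splineDesign(kn, years, ord = 4,
                             derivs = rep(order, length(years)))
  structure(B,
            knots = if (n_interior_knots > 0)
              kn[5:(4 + n_interior_knots)] else numeric(0),
            window = window)
}

#' Fit a cubic regression spline under lognormal scatter
#'
#' Fits the basis from [cubic_basis()] by ordinary least squares to
#' `log(value + offset_c)`, the lognormal scatter model for a non-negative
#' annual metric. The residual standard deviation `sigma` on the log scale
#' is estimated with divisor `n - p`; if `variance_changepoint` is set, a
#' separate sigma is estimated for years up to and after the changepoint
#' (for series whose spread shifts mid-window, e.g. annual treated area
#' around the mid-1980s), each regime's divisor apportioning the `p` model
#' degrees of freedom by its share of observations.
#'
#' @param series an `annual_series` or data frame with `year` and `value`;
#'   years with missing values are dropped.
#' @param n_interior_knots interior knot count.
#' @param offset_c positive constant added before the log when zeros occur
#'   (default 0.5); reported in the fit and subtracted back on the natural
#'   scale.
#' @param variance_changepoint year splitting the two variance regimes, or
#'   `NULL` for a single regime.
#' @return A `spline_fit` object: coefficients, interior knots, window,
#'   `n_basis`, per-regime `sigma`, `gcv` score, `offset_c`, and the data
#'   actually fitted.
#' @export
fit_spline <- function(series, n_interior_knots, offset_c = 0.5,
                       variance_changepoint = NULL) {
  d <- as.data.frame(series)[, c("year", "value")]
  d <- d[!is.na(d$value), , drop = FALSE]
  n <- nrow(d)
  if (n < 8 || length(unique(d$year)) < 8) {
    stop("need at least 8 distinct observed years to fit a spline")
  }
  if (any(d$value < 0)) stop("series values must be non-negative")
  if (any(d$value == 0) && offset_c <= 0) {
    stop("offset_c must be positive when the series contains zeros")
  }
  p <- n_interior_knots + 4
  if (p > n) stop("over-parameterized: p = ", p, " basis functions for ",
                  n, " observations")
  window <- range(d$year)
  B <- cubic_basis(d$year, n_interior_knots, window)
  z <- log(d$value + offset_c)
  fit <- lm.fit(B, z)
  if (fit$rank < p) stop("singular normal equations at k = ", n_interior_knots)
  resid <- fit$residuals
  rss <- sum(resid^2)

  if (is.null(variance_changepoint)) {
    sigma <- sqrt(rss / (n - p))
    names(sigma) <- "all"
  } else {
    pre <- d$year <= variance_changepoint
    if (!any(pre) || all(pre)) {
      stop("variance_changepoint must split the observed years")
    }
    sigma <- vapply(list(pre, !pre), function(idx) {
      n_r <- sum(idx)
      sqrt(sum(resid[idx]^2) / (n_r - p * n_r / n))
    }, numeric(1))
    names(sigma) <- c(paste0("<=", variance_changepoint),
                      paste0(">", variance_changepoint))
  }

  structure(
    list(coefficients = unname(fit$coefficients),
         knots = attr(B, "knots"),
         n_interior_knots = n_interior_knots,
         n_basis = p,
         window = window,
         offset_c = offset_c,
         sigma = sigma,
         variance_changepoint = variance_changepoint,
         gcv = n * rss / (n - p)^2,
         rss = rss,
         fitted_log = unname(fit$fitted.values),
         residuals_log = unname(resid),
         data = tibble(year = d$year, value = d$value)),
    class = "spline_fit")
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf("Cubic regression spline: %d interior knots (p = %d), window %d-%d\n",
              x$n_interior_knots, x$n_basis, x$window[1], x$window[2]))
  cat(sprintf("  offset_c = %g; GCV = %.5g\n", x$offset_c, x$gcv))
  cat("  sigma (log scale):",
      paste(sprintf("%s = %.4g", names(x$sigma), x$sigma), collapse = ", "), "\n")
  invisible(x)
}

#' Select the knot count by generalised cross-validation
#'
#' Evaluates `GCV(k) = n * RSS_k / (n - p_k)^2` on the log scale for each
#' candidate interior knot count and returns the minimiser, ties broken
#' toward the smaller (smoother) `k`. The full table is returned for audit.
#'
#' @inheritParams fit_spline
#' @param k_min,k_max candidate interior knot range; `k_max = NULL` defaults
#'   to `min(35, floor(n/3) - 4)`, wide enough for decadal structure on a
#'   century-long series while keeping `p <= n/3`.
#' @return List with `best_k`, `gcv_table` (tibble `k`, `p`, `gcv`), and
#'   `fit` (the refitted winner).
#' @export
select_knots <- function(series, k_min = 0, k_max = NULL, offset_c = 0.5,
                         variance_changepoint = NULL) {
  d <- as.data.frame(series)[, c("year", "value")]
  n <- sum(!is.na(d$value))
  if (is.null(k_max)) k_max <- min(35, floor(n / 3) - 4)
  ks <- seq.int(k_min, k_max)
  ks <- ks[ks + 4 <= n]
  if (!length(ks)) stop("no feasible knot counts in [", k_min, ", ", k_max, "]")
  gcv <- vapply(ks, function(k) {
    f <- try(fit_spline(series, k, offset_c, variance_changepoint),
             silent = TRUE)
    if (inherits(f, "try-error")) NA_real_ else f$gcv
  }, numeric(1))
  tab <- tibble(k = ks, p = ks + 4, gcv = gcv)
  if (all(is.na(gcv))) stop("no knot count produced a valid fit")
  best_k <- ks[which.min(gcv)]  # which.min takes the first, i.e. smallest k
  list(best_k = best_k, gcv_table = tab,
       fit = fit_spline(series, best_k, offset_c, variance_changepoint))
}

#' Evaluate a fitted spline and its derivatives
#'
#' Analytic evaluation of the fitted curve, gradient (per year), or
#' curvature (per year squared) from the piecewise-cubic coefficients.
#' On the log scale these are `s`, `s'`, `s''`; on the natural scale of the
#' metric they are `m = exp(s) - offset_c`, `m' = exp(s) s'`, and
#' `m'' = exp(s) (s'' + s'^2)`. No extrapolation: years must lie within the
#' fitted window.
#'
#' @param fit a `spline_fit`.
#' @param years evaluation years within the fitted window.
#' @param order 0 (curve), 1 (gradient), or 2 (curvature).
#' @param scale `"natural"` (default; the metric's own units) or `"log"`.
#' @return A `curve_eval` tibble with columns `year`, `value`, and
#'   attributes `order`, `scale`.
#' @export
evaluate_spline <- function(fit, years, order = 0,
                            scale = c("natural", "log")) {
  scale <- match.arg(scale)
  stopifnot(inherits(fit, "spline_fit"), order %in% 0:2)
  if (any(years < fit$window[1] | years > fit$window[2])) {
    stop("years outside the fitted window ", fit$window[1], "-",
         fit$window[2], "; no extrapolation")
  }
  basis_at <- function(ord) {
    cubic_basis(years, fit$n_interior_knots, fit$window, order = ord)
  }
  if (scale == "log") {
    value <- drop(basis_at(order) %*% fit$coefficients)
  } else {
    s0 <- drop(basis_at(0) %*% fit$coefficients)
    value <- switch(as.character(order),
      "0" = exp(s0) - fit$offset_c,
      "1" = exp(s0) * drop(basis_at(1) %*% fit$coefficients),
      "2" = {
        s1 <- drop(basis_at(1) %*% fit$coefficients)
        s2 <- drop(basis_at(2) %*% fit$coefficients)
        exp(s0) * (s2 + s1^2)
      })
  }
  structure(tibble(year = years, value = value),
            order = order, scale = scale,
            class = c("curve_eval", "tbl_df", "tbl", "data.frame"))
}
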