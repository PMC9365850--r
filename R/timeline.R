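# Parametric bootstrap bands on the fitted trend and its derivatives, and
# extraction of multi-year significant periods.

#' Timeline analysis configuration
#'
#' @param n_bootstrap parametric bootstrap replicates (>= 100; default 1000).
#' @param conf pointwise confidence level (default 0.95).
#' @param min_run minimum consecutive significant years for a reported
#'   period (default 5).
#' @param seed integer seed; every random draw in the analysis flows from it.
#' @param refit_knots if `TRUE`, re-select the knot count by GCV inside each
#'   bootstrap replicate instead of holding it at the original selection.
#' @param scale scale on which bands and significance are computed:
#'   `"natural"` (default) or `"log"`. Gradient sign calls are identical on
#'   the two scales; curvature sign calls are not.
#' @return A `timeline_config` list.
#' @export
timeline_config <- function(n_bootstrap = 1000, conf = 0.95, min_run = 5,
                            seed = 1, refit_knots = FALSE,
                            scale = c("natural", "log")) {
  scale <- match.arg(scale)
  stopifnot(n_bootstrap >= 100, conf > 0, conf < 1, min_run >= 1)
  structure(list(n_bootstrap = as.integer(n_bootstrap), conf = conf,
                 min_run = as.integer(min_run), seed = as.integer(seed),
                 refit_knots = isTRUE(refit_knots), scale = scale),
            class = "timeline_config")
}

# per-observation log-scale scatter sd under the (possibly piecewise) model
sigma_by_year <- function(fit) {
  if (is.null(fit$variance_changepoint)) {
    rep(fit$sigma[[1]], nrow(fit$data))
  } else {
    ifelse(fit$data$year <= fit$variance_changepoint,
           fit$sigma[[1]], fit$sigma[[2]])
  }
}

#' Parametric bootstrap confidence bands
#'
#' Simulates `n_bootstrap` replicate series from the fitted scatter model
#' (`z* = s_hat(t) + eps`, `eps ~ N(0, sigma_regime^2)` on the log scale),
#' refits the spline to each replicate with the original knot count (or
#' re-selects it when `refit_knots`), and takes empirical pointwise
#' quantiles of the replicate curve, gradient, and curvature as the
#' confidence bands. Deterministic given `config$seed`; replicate `b` always
#' consumes the same normal draws regardless of `n_bootstrap`, so enlarging
#' the replicate count never reshuffles earlier replicates.
#'
#' @param fit a `spline_fit`.
#' @param config a [timeline_config()].
#' @param eval_years years at which bands are evaluated; defaults to every
#'   integer year of the fitted window.
#' @param k_min,k_max knot range used only when `config$refit_knots`.
#' @return A `trend_bands` tibble: `year`, `attribute`
#'   (curve/gradient/curvature), `estimate`, `low`, `high`, `significant`,
#'   `sign`; attributes `config` and `scale`.
#' @export
bootstrap_bands <- function(fit, config = timeline_config(),
                            eval_years = NULL, k_min = 0, k_max = NULL) {
  stopifnot(inherits(fit, "spline_fit"))
  if (is.null(eval_years)) {
    eval_years <- seq.int(ceiling(fit$window[1]), floor(fit$window[2]))
  }
  nB <- config$n_bootstrap
  n <- nrow(fit$data)
  sig <- sigma_by_year(fit)
  if (all(sig < 1e-10)) {
    warning("degenerate fit with sigma = 0: bands collapse to the estimates")
  }

  set.seed(config$seed)
  # column-major fill: replicate b owns draws (b-1)*n + 1 .. b*n
  E <- matrix(rnorm(n * nB), n, nB) * sig
  Zstar <- fit$fitted_log + E

  D <- lapply(0:2, function(o)
    cubic_basis(eval_years, fit$n_interior_knots, fit$window, order = o))

  if (!config$refit_knots) {
    B <- cubic_basis(fit$data$year, fit$n_interior_knots, fit$window)
    qrB <- qr(B)
    coefs <- qr.coef(qrB, Zstar)                 # p x nB
    S0 <- D[[1]] %*% coefs
    S1 <- D[[2]] %*% coefs
    S2 <- D[[3]] %*% coefs
  } else {
    # re-select k by GCV inside every replicate, propagating the
    # model-selection step into the bands; all candidate designs share the
    # observation years, so the QR of each candidate basis is reused
    if (is.null(k_max)) k_max <- min(35, floor(n / 3) - 4)
    ks <- seq.int(k_min, k_max)
    ks <- ks[ks + 4 <= n]
    m <- length(eval_years)
    per_k <- lapply(ks, function(k) {
      Bk <- cubic_basis(fit$data$year, k, fit$window)
      qrk <- qr(Bk)
      ck <- qr.coef(qrk, Zstar)                  # p_k x nB
      rss <- colSums((Zstar - Bk %*% ck)^2)
      list(k = k, coefs = ck,
           gcv = n * rss / (n - (k + 4))^2,
           D = lapply(0:2, function(o)
             cubic_basis(eval_years, k, fit$window, order = o)))
    })
    gcv_mat <- do.call(rbind, lapply(per_k, `[[`, "gcv"))  # nk x nB
    pick <- apply(gcv_mat, 2, which.min)
    S0 <- S1 <- S2 <- matrix(NA_real_, m, nB)
    for (j in seq_along(per_k)) {
      sel <- which(pick == j)
      if (!length(sel)) next
      ck <- per_k[[j]]$coefs[, sel, drop = FALSE]
      S0[, sel] <- per_k[[j]]$D[[1]] %*% ck
      S1[, sel] <- per_k[[j]]$D[[2]] %*% ck
      S2[, sel] <- per_k[[j]]$D[[3]] %*% ck
    }
  }

  to_scale <- function(S0, S1, S2) {
    if (config$scale == "log") {
      list(curve = S0, gradient = S1, curvature = S2)
    } else {
      list(curve = exp(S0) - fit$offset_c,
           gradient = exp(S0) * S1,
           curvature = exp(S0) * (S2 + S1^2))
    }
  }
  reps <- to_scale(S0, S1, S2)

  point <- lapply(setNames(0:2, names(reps)), function(o)
    evaluate_spline(fit, eval_years, order = o, scale = config$scale)$value)

  alpha <- (1 - config$conf) / 2
  band_rows <- lapply(names(reps), function(attr) {
    qs <- t(apply(reps[[attr]], 1, quantile, probs = c(alpha, 1 - alpha),
                  type = 7, names = FALSE))
    est <- point[[attr]]
    low <- qs[, 1]; high <- qs[, 2]
    signif <- low > 0 | high < 0
    tibble(year = eval_years, attribute = attr, estimate = est,
           low = low, high = high,
           significant = signif,
           sign = ifelse(low > 0, "positive",
                         ifelse(high < 0, "negative", "none")))
  })
  out <- bind_rows(band_rows)
  structure(out, config = config, scale = config$scale,
            class = c("trend_bands", class(out)))
}

#' Extract significant periods
#'
#' Maximal runs of at least `min_run` consecutive years in which the
#' pointwise confidence interval for the gradient or curvature excludes
#' zero with a constant sign. Shorter runs are discarded.
#'
#' @param bands a `trend_bands` from [bootstrap_bands()].
#' @param min_run minimum run length in years; defaults to the value in the
#'   bands' config (5 unless overridden).
#' @return Tibble with `attribute`, `sign`, `start_year`, `end_year`,
#'   `duration`.
#' @export
significant_periods <- function(bands, min_run = NULL) {
  if (is.null(min_run)) {
    cfg <- attr(bands, "config")
    min_run <- if (is.null(cfg)) 5L else cfg$min_run
  }
  out <- list()
  for (attr_name in c("gradient", "curvature")) {
    sub <- bands[bands$attribute == attr_name, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    if (!nrow(sub)) next
    code <- ifelse(sub$significant, ifelse(sub$sign == "positive", 1L, -1L), 0L)
    r <- rle(code)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values != 0L & r$lengths >= min_run)
    for (i in keep) {
      out[[length(out) + 1L]] <- tibble(
        attribute = attr_name,
        sign = if (r$values[i] > 0) "positive" else "negative",
        start_year = sub$year[starts[i]],
        end_year = sub$year[ends[i]],
        duration = r$lengths[i])
    }
  }
  if (!length(out)) {
    return(tibble(attribute = character(), sign = character(),
                  start_year = integer(), end_year = integer(),
                  duration = integer()))
  }
  bind_rows(out)
}

#' Run the full timeline analysis on an annual series
#'
#' Composes knot selection by GCV, the lognormal-scatter spline fit, the
#' parametric bootstrap bands, and significant-period extraction, returning
#' everything with a full audit trail (chosen knot count, GCV table,
#' per-regime sigma, seed).
#'
#' @param series an `annual_series` (or data frame with `year`, `value`).
#' @param spline_options list with any of `k_min`, `k_max`, `offset_c`,
#'   `variance_changepoint`.
#' @param config a [timeline_config()].
#' @return A `timeline_result` list: `fit`, `bands`, `periods`, `audit`.
#' @export
run_timeline <- function(series, spline_options = list(),
                         config = timeline_config()) {
  opts <- modifyList(list(k_min = 0, k_max = NULL, offset_c = 0.5,
                          variance_changepoint = NULL), spline_options)
  sel <- select_knots(series, k_min = opts$k_min, k_max = opts$k_max,
                      offset_c = opts$offset_c,
                      variance_changepoint = opts$variance_changepoint)
  bands <- bootstrap_bands(sel$fit, config,
                           k_min = opts$k_min, k_max = opts$k_max)
  periods <- significant_periods(bands, config$min_run)
  structure(
    list(fit = sel$fit, bands = bands, periods = periods,
         audit = list(best_k = sel$best_k, gcv_table = sel$gcv_table,
                      sigma = sel$fit$sigma, offset_c = opts$offset_c,
                      variance_changepoint = opts$variance_changepoint,
                      seed = config$seed, n_bootstrap = config$n_bootstrap,
                      conf = config$conf, min_run = config$min_run,
                      scale = config$scale,
                      metric = attr(series, "metric"),
                      mode = attr(series, "mode"))),
    class = "timeline_result")
}

#' @export
print.timeline_result <- function(x, ...) {
  a <- x$audit
  cat(sprintf("Timeline analysis%s: k = %d knots, sigma = %s, seed = %s\n",
              if (!is.null(a$metric)) paste0(" [", a$metric, "]") else "",
              a$best_k,
              paste(sprintf("%.3g", x$fit$sigma), collapse = "/"),
              a$seed))
  if (nrow(x$periods)) {
    cat("Significant periods (>=", a$min_run, "consecutive years):\n")
    for (i in seq_len(nrow(x$periods))) {
      p <- x$periods[i, ]
      cat(sprintf("  %s %s: %d-%d (%d years)\n", p$sign, p$attribute,
                  p$start_year, p$end_year, p$duration))
    }
  } else {
    cat("No significant periods of length >=", a$min_run, "years\n")
  }
  invisible(x)
}

#' Write trend bands and periods as tidy CSV
#'
#' @param result a `timeline_result`.
#' @param bands_path,periods_path output CSV paths (`NULL` to skip one).
#' @return Invisibly, the paths written.
#' @export
write_timeline <- function(result, bands_path = NULL, periods_path = NULL) {
  if (!is.null(bands_path)) {
    b <- as.data.frame(result$bands)
    b$scale <- attr(result$bands, "scale")
    write.csv(b, bands_path, row.names = FALSE)
  }
  if (!is.null(periods_path)) {
    write.csv(as.data.frame(result$periods), periods_path, row.names = FALSE)
  }
  invisible(c(bands_path, periods_path))
}
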