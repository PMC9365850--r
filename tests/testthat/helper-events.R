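# Builders and independent brute-force oracles used across the suite.

make_event <- function(island_id = "NZ-001", country = "NZ", area_ha = 100,
                       habitation = "0", target_species = "Rattus rattus",
                       status = "successful", end_year = 2000L,
                       primary_method = "Tx", data_quality = "good",
                       whole_island = TRUE, feral = TRUE,
                       purpose_eradication = TRUE, island_name = NA_character_) {
  tibble::tibble(island_id, island_name, country, area_ha, habitation,
                 target_species, status, end_year, primary_method,
                 data_quality, whole_island, feral, purpose_eradication)
}

make_events <- function(n, ...) {
  args <- list(...)
  base <- dplyr::bind_rows(lapply(seq_len(n), function(i) make_event()))
  for (nm in names(args)) base[[nm]] <- rep_len(args[[nm]], n)
  base
}

# brute-force re-check of every inclusion rule for one event row
oracle_passes_all_rules <- function(e) {
  e$data_quality %in% c("good", "satisfactory") &&
    isTRUE(e$whole_island) && isTRUE(e$feral) &&
    isTRUE(e$purpose_eradication) &&
    e$status %in% status_levels()
}

# independent year-bucket tally
oracle_year_counts <- function(event_years, years) {
  vapply(years, function(y) sum(event_years == y, na.rm = TRUE), numeric(1))
}

# exhaustive run-length scan over a signed significance vector
oracle_runs <- function(code, min_run) {
  runs <- list()
  i <- 1
  n <- length(code)
  while (i <= n) {
    j <- i
    while (j < n && code[j + 1] == code[i]) j <- j + 1
    if (code[i] != 0 && (j - i + 1) >= min_run) {
      runs[[length(runs) + 1]] <- c(start = i, end = j, sign = code[i])
    }
    i <- j + 1
  }
  runs
}

# Wilson interval by numeric inversion of the score test
oracle_wilson <- function(x, n, conf) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  score <- function(p) (phat - p) / sqrt(p * (1 - p) / n)
  lo <- if (phat == 0) 0 else
    uniroot(function(p) score(p) - z, c(1e-12, min(phat, 1 - 1e-9)),
            tol = 1e-12)$root
  hi <- if (phat == 1) 1 else
    uniroot(function(p) score(p) + z, c(max(phat, 1e-9), 1 - 1e-12),
            tol = 1e-12)$root
  c(lo, hi)
}

# GCV grid computed through an independent basis construction (splines::bs
# inside lm); same column space as the package basis, so same RSS
oracle_gcv_grid <- function(d, ks, offset_c) {
  window <- range(d$year)
  z <- log(d$value + offset_c)
  n <- nrow(d)
  vapply(ks, function(k) {
    interior <- if (k > 0) window[1] + seq_len(k) * diff(window) / (k + 1)
                else numeric(0)
    X <- splines::bs(d$year, knots = interior, degree = 3, intercept = TRUE,
                     Boundary.knots = window)
    fit <- lm(z ~ X - 1)
    rss <- sum(residuals(fit)^2)
    n * rss / (n - (k + 4))^2
  }, numeric(1))
}
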