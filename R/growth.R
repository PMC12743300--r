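## Growth kinetics from cell-count time series: exponential-window
## detection, log-linear growth-rate regression, lag and stationary
## summaries, generation counting, and a balanced two-way ANOVA.

#' Construct a growth series
#'
#' One replicate's cell-count trajectory at one assay temperature.
#'
#' @param day numeric vector of sampling days, strictly increasing.
#' @param cells_per_ml cell concentrations (cells/ml), all > 0.
#' @param sample_id sample identifier.
#' @param replicate replicate number.
#' @param temperature_c assay temperature (deg C).
#' @return An object of class `growth_series`.
#' @export
growth_series <- function(day, cells_per_ml, sample_id = "S1",
                          replicate = 1L, temperature_c = NA_real_) {
  day <- as.numeric(day); cells <- as.numeric(cells_per_ml)
  if (length(day) != length(cells) || length(day) < 2L)
    stop_pt("a growth series needs >= 2 (day, count) observations",
            class = "invalid_parameter")
  if (any(diff(day) <= 0))
    stop_pt("days must be strictly increasing", class = "invalid_parameter")
  if (any(!is.finite(cells)) || any(cells <= 0))
    stop_pt("cell counts must be positive", class = "invalid_parameter")
  structure(list(sample_id = as.character(sample_id),
                 replicate = as.integer(replicate),
                 temperature_c = as.numeric(temperature_c),
                 observations = data.frame(day = day,
                                           cells_per_ml = cells)),
            class = "growth_series")
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("Growth series %s rep %d @ %g degC: %d observations, days %g-%g\n",
              x$sample_id, x$replicate, x$temperature_c,
              nrow(x$observations), min(x$observations$day),
              max(x$observations$day)))
  invisible(x)
}

## OLS of ln(count) on day; returns slope, stderr, r2 with the convention
## that a window fitted exactly (zero total or residual variation) has
## r2 = 1 and stderr 0
loglinear_fit <- function(day, cells) {
  y <- log(cells)
  n <- length(y)
  xb <- mean(day); yb <- mean(y)
  sxx <- sum((day - xb)^2)
  slope <- sum((day - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  resid <- y - (intercept + slope * day)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - yb)^2)
  r2 <- if (ss_tot <= .Machine$double.eps * max(1, sum(y^2))) 1
        else 1 - ss_res / ss_tot
  r2 <- min(max(r2, 0), 1)
  stderr <- if (n > 2L) sqrt(ss_res / (n - 2L) / sxx) else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2, stderr = stderr, n = n)
}

#' Detect the exponential-phase window of a growth series
#'
#' Enumerates every contiguous window of at least `min_points` consecutive
#' observations, fits ln(count) ~ day by OLS in each, and returns the
#' window with the largest slope among windows whose R^2 meets
#' `r2_threshold`. If no window qualifies, the window maximising R^2 is
#' returned instead. Ties are broken by the longer window, then the earlier
#' start. A window that is fitted exactly (e.g. perfectly flat) counts as
#' R^2 = 1.
#'
#' @param series a [growth_series()].
#' @param min_points minimum window length (default 3).
#' @param r2_threshold R^2 needed for a window to qualify (default 0.95).
#' @return Named numeric `c(first_day, last_day)` with attribute
#'   `"qualified"` indicating whether any window met the threshold.
#' @export
detect_exponential_phase <- function(series, min_points = 3L,
                                     r2_threshold = 0.95) {
  obs <- series$observations
  n <- nrow(obs)
  if (n < min_points)
    stop_pt("series has %d observations; need >= %d", n, min_points,
            class = "insufficient_data")
  wins <- list()
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq.int(i + min_points - 1L, n)) {
      f <- loglinear_fit(obs$day[i:j], obs$cells_per_ml[i:j])
      wins[[length(wins) + 1L]] <-
        data.frame(i = i, j = j, len = j - i + 1L,
                   slope = f$slope, r2 = f$r2)
    }
  }
  wins <- do.call(rbind, wins)
  qualified <- wins[wins$r2 >= r2_threshold, , drop = FALSE]
  pick_best <- function(tab, key) {
    best <- tab[abs(tab[[key]] - max(tab[[key]])) <= 1e-12, , drop = FALSE]
    best <- best[best$len == max(best$len), , drop = FALSE]
    best[which.min(best$i), , drop = FALSE]
  }
  any_qual <- nrow(qualified) > 0L
  best <- if (any_qual) pick_best(qualified, "slope") else pick_best(wins, "r2")
  out <- c(first_day = obs$day[best$i], last_day = obs$day[best$j])
  attr(out, "qualified") <- any_qual
  out
}

#' Estimate the specific growth rate of a series
#'
#' The specific growth rate is the slope of the OLS regression of
#' ln(cell concentration) on experimental day over the exponential window
#' (auto-detected with [detect_exponential_phase()] unless `window` is
#' given).
#'
#' @param series a [growth_series()].
#' @param window optional `c(first_day, last_day)`; observations with
#'   `first_day <= day <= last_day` are used.
#' @param min_points,r2_threshold passed to [detect_exponential_phase()]
#'   when `window` is NULL.
#' @return An object of class `growth_rate_estimate`: list with `mu`
#'   (day^-1), `window`, `r_squared`, `stderr`, `n_points`.
#' @examples
#' s <- growth_series(0:4, 3e5 * 2^(0:4))
#' growth_rate(s)$mu   # ln 2
#' @export
growth_rate <- function(series, window = NULL, min_points = 3L,
                        r2_threshold = 0.95) {
  if (is.null(window))
    window <- detect_exponential_phase(series, min_points, r2_threshold)
  obs <- series$observations
  sel <- obs$day >= window[1] & obs$day <= window[2]
  if (sum(sel) < 3L)
    stop_pt("window contains %d points; need >= 3", sum(sel),
            class = "insufficient_data")
  d <- obs[sel, ]
  if (any(d$cells_per_ml <= 0))
    stop_pt("window contains non-positive counts", class = "invalid_data")
  f <- loglinear_fit(d$day, d$cells_per_ml)
  structure(list(mu = f$slope,
                 window = c(first_day = unname(window[1]),
                            last_day = unname(window[2])),
                 r_squared = f$r2, stderr = f$stderr, n_points = f$n),
            class = "growth_rate_estimate")
}

#' @export
print.growth_rate_estimate <- function(x, ...) {
  cat(sprintf("mu = %.4g /d (SE %.3g, R2 %.4f, n = %d, days %g-%g)\n",
              x$mu, x$stderr, x$r_squared, x$n_points,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Maximum observed cell count of a series
#'
#' The stationary-phase ceiling reached by a trajectory, taken as the
#' maximum observed count.
#'
#' @param series a [growth_series()].
#' @return cells/ml.
#' @export
stationary_max <- function(series) {
  max(series$observations$cells_per_ml)
}

#' Lag time of a growth series
#'
#' First sampled day at which the count reaches `fold_threshold` times the
#' initial count. If never reached, the last day is returned with
#' `reached = FALSE`.
#'
#' @param series a [growth_series()].
#' @param fold_threshold fold change over the initial density that ends the
#'   lag (default 2).
#' @return List with `days` and logical `reached`.
#' @export
lag_time <- function(series, fold_threshold = 2.0) {
  obs <- series$observations
  hit <- which(obs$cells_per_ml >= fold_threshold * obs$cells_per_ml[1])
  if (length(hit) == 0L)
    list(days = obs$day[nrow(obs)], reached = FALSE)
  else
    list(days = obs$day[hit[1]], reached = TRUE)
}

#' Number of generations from a growth rate and a duration
#'
#' Generations = mu * duration / ln 2 (doublings).
#'
#' @param mu specific growth rate (day^-1).
#' @param duration elapsed time (days), >= 0.
#' @return Generation count.
#' @examples
#' generations(log(2), 10)  # 10
#' @export
generations <- function(mu, duration) {
  check_number(duration, "duration", lower = 0)
  mu * duration / log(2)
}

#' Balanced fixed-effects two-way ANOVA with interaction
#'
#' Standard balanced-design sums-of-squares decomposition for a two-factor
#' fixed-effects model with interaction, e.g. strain selection x assay
#' temperature. Only balanced designs with replication are supported;
#' anything else errors.
#'
#' @param response numeric response values.
#' @param factor_a,factor_b factor labels (coerced to factor), same length
#'   as `response`.
#' @return A data.frame with one row per effect (`A`, `B`, `A:B`,
#'   `Residuals`): `ss`, `df`, `F`, `p` (`F`/`p` are NA for residuals).
#'   Attribute `"ss_total"` carries the total sum of squares.
#' @export
two_way_anova <- function(response, factor_a, factor_b) {
  y <- as.numeric(response)
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (length(y) != length(fa) || length(y) != length(fb))
    stop_pt("response and factors must have equal length",
            class = "invalid_parameter")
  tab <- table(fa, fb)
  if (any(tab == 0L))
    stop_pt("design has empty cells; only complete designs are supported",
            class = "unbalanced_design")
  r <- unique(as.vector(tab))
  if (length(r) != 1L)
    stop_pt("design is unbalanced; only balanced designs are supported",
            class = "unbalanced_design")
  if (r < 2L)
    stop_pt("design has no replication (one observation per cell)",
            class = "unbalanced_design")
  A <- nlevels(fa); B <- nlevels(fb)
  g <- mean(y)
  ma <- tapply(y, fa, mean)
  mb <- tapply(y, fb, mean)
  mcell <- tapply(y, list(fa, fb), mean)
  ss_a <- B * r * sum((ma - g)^2)
  ss_b <- A * r * sum((mb - g)^2)
  inter <- sweep(sweep(mcell, 1, ma, "-"), 2, mb, "-") + g
  ss_ab <- r * sum(inter^2)
  ss_w <- sum((y - mcell[cbind(fa, fb)])^2)
  ss_tot <- sum((y - g)^2)
  df_w <- A * B * (r - 1L)
  effs <- data.frame(
    effect = c("A", "B", "A:B", "Residuals"),
    ss = c(ss_a, ss_b, ss_ab, ss_w),
    df = c(A - 1L, B - 1L, (A - 1L) * (B - 1L), df_w))
  ms_w <- ss_w / df_w
  Fval <- if (ms_w == 0) ifelse(effs$ss == 0, 0, Inf)
          else (effs$ss / effs$df) / ms_w
  Fval[effs$ss == 0] <- 0
  pval <- stats::pf(Fval, effs$df, df_w, lower.tail = FALSE)
  pval[Fval == 0] <- 1
  pval[is.infinite(Fval)] <- 0
  effs$F <- c(Fval[1:3], NA)
  effs$p <- c(pval[1:3], NA)
  attr(effs, "ss_total") <- ss_tot
  effs
}
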