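## Multi-start least-squares fitting of the Norberg curve.

#' Fit the Norberg thermal performance curve by multi-start least squares
#'
#' Estimates (a, b, z, w) by minimising the sum of squared residuals over a
#' grid of initialisations. Positivity of `a` and `w` is enforced by fitting
#' on the log scale; `b` is unconstrained (it may come out <= 0 for a
#' symmetric or cold-skewed curve). Negative observed rates are retained:
#' they carry the information that locates the critical thermal limits.
#'
#' The default start grid places `z` at the observed-temperature quartiles,
#' `w` at 0.8/1.2/1.6 times the observed span, `b` at 0 and 0.063 (the
#' canonical Eppley exponent), and rescales `a` so each candidate curve
#' touches the observed maximum. The lowest-SSR solution wins; SSR ties are
#' broken by the smallest parameter norm.
#'
#' @param observations data.frame with columns `temperature` (or
#'   `temperature_c`) and `growth_rate` (or `growth_rate_per_day`), or a
#'   two-column matrix. At least 4 observations over at least 3 distinct
#'   temperatures.
#' @param starts optional data.frame of start values with columns
#'   `a`, `b`, `z`, `w` replacing the default grid.
#' @param tol relative convergence tolerance passed to the optimiser.
#' @return An object of class `norberg_fit`: list with `params`
#'   ([norberg_params()]), `ssr`, `n_obs`, `converged`, `n_starts_tried`.
#' @examples
#' p <- norberg_params(0.7548, 0.03704, 26.195, 23.99)
#' temps <- c(16, 18, 22, 24, 26, 30, 34, 36, 38)
#' obs <- data.frame(temperature = temps, growth_rate = norberg_growth(temps, p))
#' fit_norberg(obs)$params   # recovers p
#' @export
fit_norberg <- function(observations, starts = NULL, tol = 1e-12) {
  obs <- normalize_observations(observations)
  temps <- obs$temperature
  rates <- obs$growth_rate
  if (length(rates) < 4L || length(unique(temps)) < 3L)
    stop_pt("need >= 4 observations spanning >= 3 distinct temperatures",
            class = "insufficient_data")
  if (all(rates <= 0))
    stop_pt("all growth rates are <= 0; cannot fit a performance curve",
            class = "degenerate_data")

  ## theta = (log a, b, z, log w)
  ssr_fun <- function(theta) {
    a <- exp(theta[1]); b <- theta[2]; z <- theta[3]; w <- exp(theta[4])
    u <- (temps - z) / (w / 2)
    r <- a * exp(b * temps) * (1 - u^2) - rates
    sum(r * r)
  }

  if (is.null(starts)) starts <- default_start_grid(temps, rates)
  best <- NULL
  n_tried <- 0L
  for (i in seq_len(nrow(starts))) {
    s <- starts[i, ]
    if (!is.finite(s$a) || s$a <= 0 || s$w <= 0) next
    theta0 <- c(log(s$a), s$b, s$z, log(s$w))
    fit <- tryCatch({
      nm <- stats::optim(theta0, ssr_fun, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = tol))
      stats::optim(nm$par, ssr_fun, method = "BFGS",
                   control = list(maxit = 500, reltol = tol))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    n_tried <- n_tried + 1L
    cand <- list(theta = fit$par, ssr = fit$value,
                 converged = fit$convergence == 0L)
    if (is.null(best) || cand$ssr < best$ssr - 1e-14 ||
        (abs(cand$ssr - best$ssr) <= 1e-14 &&
         sum(cand$theta^2) < sum(best$theta^2))) {
      best <- cand
    }
  }
  if (is.null(best))
    stop_pt("no optimisation start converged", class = "fit_failure")

  params <- norberg_params(a = exp(best$theta[1]), b = best$theta[2],
                           z = best$theta[3], w = exp(best$theta[4]))
  structure(list(params = params, ssr = best$ssr,
                 n_obs = length(rates), converged = best$converged,
                 n_starts_tried = n_tried),
            class = "norberg_fit")
}

#' @export
print.norberg_fit <- function(x, ...) {
  cat(sprintf("Norberg fit: n = %d, SSR = %.4g, %d starts, converged: %s\n",
              x$n_obs, x$ssr, x$n_starts_tried, x$converged))
  print(x$params)
  invisible(x)
}

normalize_observations <- function(observations) {
  if (is.matrix(observations)) {
    observations <- data.frame(temperature = observations[, 1],
                               growth_rate = observations[, 2])
  }
  obs <- as.data.frame(observations)
  tcol <- intersect(c("temperature", "temperature_c"), names(obs))[1]
  rcol <- intersect(c("growth_rate", "growth_rate_per_day", "rate"),
                    names(obs))[1]
  if (is.na(tcol) || is.na(rcol))
    stop_pt("observations need temperature and growth_rate columns",
            class = "invalid_parameter")
  out <- data.frame(temperature = as.numeric(obs[[tcol]]),
                    growth_rate = as.numeric(obs[[rcol]]))
  out <- out[stats::complete.cases(out), , drop = FALSE]
  out
}

default_start_grid <- function(temps, rates) {
  span <- diff(range(temps))
  if (span <= 0) span <- 1
  zs <- unname(stats::quantile(temps, c(0.25, 0.5, 0.75)))
  ws <- span * c(0.8, 1.2, 1.6)
  bs <- c(0, 0.063)
  grid <- expand.grid(b = bs, z = zs, w = ws)
  rmax <- max(rates)
  grid$a <- vapply(seq_len(nrow(grid)), function(i) {
    shape <- exp(grid$b[i] * temps) *
      (1 - ((temps - grid$z[i]) / (grid$w[i] / 2))^2)
    peak <- max(shape)
    if (peak > 0 && rmax > 0) rmax / peak else 1
  }, numeric(1))
  grid[, c("a", "b", "z", "w")]
}
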