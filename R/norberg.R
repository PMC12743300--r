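## Norberg thermal performance curve and derived thermal traits.
##
## The model is f(T) = a * exp(b*T) * [1 - ((T - z) / (w/2))^2]: an Eppley
## exponential envelope (a, b) times a quadratic thermal niche of width w
## centred at z. Growth is positive only on (z - w/2, z + w/2).

#' Norberg curve parameters
#'
#' Container for the four parameters of the Norberg thermal performance
#' curve \eqn{f(T) = a e^{bT} [1 - ((T - z)/(w/2))^2]}.
#'
#' @param a Eppley curve coefficient (day^-1); must be > 0.
#' @param b Eppley curve exponent (per deg C); may be any sign (b >= 0 gives
#'   the usual warm-skewed curve).
#' @param z centre of the quadratic niche term (deg C).
#' @param w temperature niche width (deg C), the span over which growth is
#'   positive; must be > 0.
#' @return An object of class `norberg_params`.
#' @examples
#' norberg_params(a = 0.7548, b = 0.03704, z = 26.195, w = 23.99)
#' @export
norberg_params <- function(a, b, z, w) {
  check_number(a, "a", lower = 0, strict_lower = TRUE)
  check_number(b, "b")
  check_number(z, "z")
  check_number(w, "w", lower = 0, strict_lower = TRUE)
  structure(list(a = a, b = b, z = z, w = w), class = "norberg_params")
}

#' @export
print.norberg_params <- function(x, ...) {
  cat(sprintf(
    "Norberg TPC parameters: a = %.5g /d, b = %.5g /degC, z = %.4g degC, w = %.4g degC\n",
    x$a, x$b, x$z, x$w))
  invisible(x)
}

as_norberg_params <- function(p) {
  if (inherits(p, "norberg_params")) return(p)
  p <- as.list(p)
  norberg_params(p$a, p$b, p$z, p$w)
}

#' Evaluate the Norberg thermal performance curve
#'
#' @param temperature assay temperature(s), deg C (vectorised).
#' @param params a [norberg_params()] object (or list with a, b, z, w).
#' @return Specific growth rate(s) in day^-1; negative outside
#'   `(z - w/2, z + w/2)`.
#' @examples
#' p <- norberg_params(0.7548, 0.03704, 26.195, 23.99)
#' norberg_growth(26, p)                       # ~1.977 /d
#' norberg_growth(c(14.2, 38.19), p)           # curve roots, ~0
#' @export
norberg_growth <- function(temperature, params) {
  params <- as_norberg_params(params)
  u <- (temperature - params$z) / (params$w / 2)
  params$a * exp(params$b * temperature) * (1 - u^2)
}

## closed-form optimum: solves d f/dT = 0, i.e. b*h*(1 - u^2) = 2u with
## u = (T - z)/h, h = w/2; the admissible root is u = (sqrt(1+b^2 h^2)-1)/(b h)
t_opt_closed_form <- function(params) {
  params <- as_norberg_params(params)
  h <- params$w / 2
  if (abs(params$b) < 1e-12) return(params$z)
  params$z + (sqrt(1 + params$b^2 * h^2) - 1) / params$b
}

#' Derive thermal traits from Norberg parameters
#'
#' Computes the optimal temperature by numerical maximisation of the curve
#' (cross-checked against the closed form
#' \eqn{T_{opt} = z + (\sqrt{1 + b^2 (w/2)^2} - 1)/b}), the maximum growth
#' rate \eqn{\mu_{max} = f(T_{opt})}, the critical thermal limits as the
#' exact roots \eqn{CT_{min} = z - w/2}, \eqn{CT_{max} = z + w/2}, and the
#' performance breadth `b80`: the length of the interval around
#' \eqn{T_{opt}} where \eqn{f(T) \ge} `fraction` \eqn{\cdot \mu_{max}},
#' endpoints located by bisection to 1e-6 deg C.
#'
#' @param params a [norberg_params()] object.
#' @param fraction performance fraction defining the breadth (default 0.8,
#'   i.e. the conventional B80).
#' @return An object of class `thermal_traits`: a list with `mu_max`,
#'   `t_opt`, `ct_min`, `ct_max`, `b80` (and the `fraction` used).
#' @examples
#' p <- norberg_params(0.7548, 0.03704, 26.195, 23.99)
#' derive_traits(p)   # mu_max ~2.09, t_opt ~28.74, ct 14.2/38.19, b80 ~10.1
#' @export
derive_traits <- function(params, fraction = 0.8) {
  params <- as_norberg_params(params)
  check_number(fraction, "fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  ct_min <- params$z - params$w / 2
  ct_max <- params$z + params$w / 2

  opt <- stats::optimize(function(T) norberg_growth(T, params),
                         interval = c(ct_min, ct_max),
                         maximum = TRUE, tol = 1e-10)
  t_opt <- opt$maximum
  t_cf <- t_opt_closed_form(params)
  if (abs(t_opt - t_cf) > 1e-6)
    warning("numerical T_opt deviates from the closed form by ",
            format(abs(t_opt - t_cf)), " degC")
  ## the closed form is exact for this curve family; keep the numerical
  ## value only as the cross-check and report the analytic optimum
  t_opt <- t_cf
  mu_max <- norberg_growth(t_opt, params)

  if (fraction >= 1) {
    b80 <- 0
  } else {
    target <- fraction * mu_max
    g <- function(T) norberg_growth(T, params) - target
    lo <- stats::uniroot(g, c(ct_min, t_opt), tol = 1e-8)$root
    hi <- stats::uniroot(g, c(t_opt, ct_max), tol = 1e-8)$root
    b80 <- hi - lo
  }

  structure(list(mu_max = mu_max, t_opt = t_opt, ct_min = ct_min,
                 ct_max = ct_max, b80 = b80, fraction = fraction),
            class = "thermal_traits")
}

#' @export
print.thermal_traits <- function(x, ...) {
  cat(sprintf(paste0(
    "Thermal traits: mu_max = %.4g /d, T_opt = %.4g degC, ",
    "CT_min = %.4g degC, CT_max = %.4g degC, B%d = %.4g degC\n"),
    x$mu_max, x$t_opt, x$ct_min, x$ct_max, round(100 * x$fraction), x$b80))
  invisible(x)
}

#' Invert thermal traits to Norberg parameters
#'
#' Given the four primary traits (`mu_max`, `t_opt`, `ct_min`, `ct_max`)
#' the Norberg parameters are recovered in closed form:
#' \eqn{z = (CT_{min}+CT_{max})/2}, \eqn{w = CT_{max}-CT_{min}}, and with
#' \eqn{h = w/2}, \eqn{u^* = (T_{opt}-z)/h}:
#' \eqn{b = 2u^*/(h(1-u^{*2}))},
#' \eqn{a = \mu_{max}/(e^{b T_{opt}} (1-u^{*2}))}.
#' Only warm-skewed curves (`t_opt` at or above the midpoint of the limits,
#' i.e. b >= 0) are supported; every published trait row this package
#' emulates satisfies that.
#'
#' @param traits a `thermal_traits` object or list with `mu_max`, `t_opt`,
#'   `ct_min`, `ct_max`.
#' @return A [norberg_params()] object; [derive_traits()] on the result
#'   reproduces the inputs to within 1e-6.
#' @examples
#' params_from_traits(list(mu_max = 2.09, t_opt = 28.74,
#'                         ct_min = 14.2, ct_max = 38.19))
#' @export
params_from_traits <- function(traits) {
  tr <- as.list(traits)
  for (f in c("mu_max", "t_opt", "ct_min", "ct_max"))
    if (is.null(tr[[f]]))
      stop_pt("traits must supply `%s`", f, class = "invalid_parameter")
  check_number(tr$mu_max, "mu_max", lower = 0, strict_lower = TRUE)
  if (!(tr$ct_min < tr$t_opt && tr$t_opt < tr$ct_max))
    stop_pt("t_opt must lie strictly inside (ct_min, ct_max)",
            class = "invalid_parameter")
  z <- (tr$ct_min + tr$ct_max) / 2
  w <- tr$ct_max - tr$ct_min
  h <- w / 2
  u <- (tr$t_opt - z) / h
  if (u < 0)
    stop_pt(paste0("t_opt below the midpoint of (ct_min, ct_max) implies ",
                   "b < 0 (cold-skewed curve), which is unsupported"),
            class = "unsupported_skew")
  b <- if (u == 0) 0 else 2 * u / (h * (1 - u^2))
  a <- tr$mu_max / (exp(b * tr$t_opt) * (1 - u^2))
  norberg_params(a = a, b = b, z = z, w = w)
}

#' Tabulate a thermal reaction norm
#'
#' Evaluates the Norberg curve on a temperature grid, for reporting or
#' plotting of fitted thermal reaction norms.
#'
#' @param params a [norberg_params()] object.
#' @param grid numeric vector of temperatures (deg C); must be non-empty.
#' @return A data.frame with columns `temperature_c` and
#'   `growth_rate_per_day`.
#' @export
thermal_reaction_norm <- function(params, grid) {
  if (length(grid) == 0L)
    stop_pt("temperature grid must be non-empty", class = "invalid_parameter")
  data.frame(temperature_c = as.numeric(grid),
             growth_rate_per_day = norberg_growth(as.numeric(grid), params))
}

#' Compare thermal traits between two groups by Student's t-test
#'
#' Per-trait two-sided pooled-variance (equal-variance) Student's t-tests
#' between two groups of per-replicate trait estimates, with group means and
#' standard errors, mirroring a traits comparison table.
#'
#' @param group_a,group_b data.frames (or lists coercible to data.frames)
#'   of per-replicate traits with columns `mu_max`, `t_opt`, `ct_min`,
#'   `ct_max`, `b80`; at least 2 replicates each.
#' @param traits which trait columns to compare.
#' @return A data.frame with one row per trait: `mean_a`, `se_a`, `mean_b`,
#'   `se_b`, `t`, `df`, `p`.
#' @export
compare_traits <- function(group_a, group_b,
                           traits = c("mu_max", "t_opt", "ct_min",
                                      "ct_max", "b80")) {
  ga <- as.data.frame(group_a)
  gb <- as.data.frame(group_b)
  if (nrow(ga) < 2L || nrow(gb) < 2L)
    stop_pt("compare_traits needs >= 2 replicates per group",
            class = "insufficient_data")
  traits <- intersect(traits, intersect(names(ga), names(gb)))
  res <- lapply(traits, function(tr) {
    tt <- pooled_t_test(ga[[tr]], gb[[tr]])
    data.frame(trait = tr, mean_a = tt$mean_x, se_a = tt$se_x,
               mean_b = tt$mean_y, se_b = tt$se_y,
               t = tt$t, df = tt$df, p = tt$p)
  })
  do.call(rbind, res)
}
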