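# ---- internal helpers along a characteristic (cohort) line -----------------
#
# All integrals of the forward model run along the line t - a = const: a
# subject aged a at time t was aged x at time c + x with c = t - a.  The
# integrands below are therefore functions of age x alone once c is fixed.

# m0 + i along the characteristic through (t, a)
outflow_on_characteristic <- function(rates, c_line) {
  function(x) eval_rate(rates$mortality_healthy, c_line + x, x) +
    eval_rate(rates$incidence, c_line + x, x)
}

# m0 alone along the characteristic
m0_on_characteristic <- function(rates, c_line) {
  function(x) eval_rate(rates$mortality_healthy, c_line + x, x)
}

# Duration breakpoints of the relative-mortality profile that fall strictly
# inside (0, dmax); integrals over duration are split there because the
# integrand has kinks (piecewise-constant R).
profile_breaks <- function(rates, dmax) {
  if (is.null(rates$relative_mortality)) return(numeric())
  b <- rates$relative_mortality$breakpoints
  b[b > 0 & b < dmax]
}

# quadrature split at interior break points (kinks of the integrand);
# rule = romberg_quad for fully smooth integrands, simpson_total for those
# involving the cached cumulative-hazard interpolants
quad_split <- function(f, lower, upper, breaks, settings, rule = romberg_quad) {
  pts <- sort(unique(c(lower, breaks[breaks > lower & breaks < upper], upper)))
  nseg <- length(pts) - 1L
  tot <- 0
  for (k in seq_len(nseg)) {
    lo <- pts[k]
    hi <- pts[k + 1L]
    # integrands are right-continuous at their break points, so on every
    # segment but the last the upper endpoint must see the left-limit value:
    # nudge it inward by a relatively negligible amount
    g <- if (k < nseg) {
      eps <- (hi - lo) * 1e-12
      function(x) f(pmin(x, hi - eps))
    } else {
      f
    }
    tot <- tot + rule(g, lo, hi, settings)
  }
  tot
}

# M1(t, a, delta) for a vector of durations delta, using a cached cumulative
# m0-hazard G along the characteristic (profile representation only).
# M1(t,a,d) = int_0^d R(tau) m0(t-d+tau, a-d+tau) dtau; substituting age
# x = a - d + tau turns each constant-R piece into a difference of G.
m1_cumhaz_profile <- function(rates, a, delta, G) {
  prof <- rates$relative_mortality
  vals <- c(prof$values, prof$default_value)
  edges <- c(0, prof$breakpoints, Inf)
  out <- numeric(length(delta))
  for (k in seq_along(vals)) {
    lo <- pmin(edges[k], delta)        # duration interval [lo, hi) clipped
    hi <- pmin(edges[k + 1L], delta)
    grow <- hi > lo
    if (any(grow))
      out[grow] <- out[grow] + vals[k] *
        (G(a - delta[grow] + hi[grow]) - G(a - delta[grow] + lo[grow]))
  }
  out
}

# ---- exported operations ---------------------------------------------------

#' Cumulative diseased-mortality hazard over a disease spell
#'
#' Computes \eqn{M_1(t, a, d) = \int_0^d m_1(t-d+\tau,\, a-d+\tau,\, \tau)\,
#' \mathrm{d}\tau}, the cumulative mortality hazard accumulated by a subject
#' aged `a` at time `t` over the last `d` years, i.e. since disease onset at
#' age `a - d`.
#'
#' @param rates An [illness_death_rates()].
#' @param t Calendar time, years since the time origin.
#' @param a Age in years.
#' @param d Disease duration in years, `0 <= d <= a`.
#' @param settings A [quadrature_settings()].
#' @return Dimensionless cumulative hazard (nonnegative, nondecreasing in
#'   `d`).
#' @export
cumulative_duration_hazard <- function(rates, t, a, d,
                                       settings = quadrature_settings()) {
  stopifnot(inherits(rates, "illness_death_rates"))
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > a)
    stop("'d' must satisfy 0 <= d <= a", call. = FALSE)
  if (d == 0) return(0)
  f <- function(tau) eval_m1(rates, t - d + tau, a - d + tau, tau)
  quad_split(f, 0, d, profile_breaks(rates, d), settings)
}

#' Survival in the healthy state
#'
#' Probability that a subject of the birth cohort through `(t, a)` is still
#' alive and disease-free at age `a`:
#' \eqn{\exp(-\int_0^a m_0 + i \,\mathrm{d}\tau)} along the characteristic,
#' with the cohort size normalised to 1 at birth.
#'
#' @inheritParams cumulative_duration_hazard
#' @return A proportion in `(0, 1]`, strictly decreasing in `a` for positive
#'   hazards.
#' @export
survival_healthy <- function(rates, t, a, settings = quadrature_settings()) {
  stopifnot(inherits(rates, "illness_death_rates"))
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0)
    stop("'a' must be a single nonnegative age", call. = FALSE)
  if (a == 0) return(1)
  f <- outflow_on_characteristic(rates, t - a)
  # the incidence switches on at its minimum age: split there, the jump
  # would otherwise defeat the extrapolation
  a_min <- max(incidence_min_age(rates), 0)
  exp(-quad_split(f, 0, a, a_min, settings))
}

#' Duration-averaged mortality of the diseased
#'
#' The effective mortality \eqn{m_1^*(t, a)} of the diseased pool: the mean
#' of \eqn{m_1(t, a, d)} weighted by the duration density
#' \eqn{C(t, a, d)} of the prevalent cases, or 0 where the pool is empty.
#' For a duration-independent \eqn{m_1} this reduces exactly to
#' \eqn{m_1(t, a)}; with a constant relative mortality \eqn{R} it is
#' \eqn{R\, m_0(t, a)}.
#'
#' @inheritParams cumulative_duration_hazard
#' @return Hazard per person-year, bounded by the range of
#'   \eqn{m_1(t, a, \cdot)}.
#' @export
m1_star <- function(rates, t, a, settings = quadrature_settings()) {
  stopifnot(inherits(rates, "illness_death_rates"))
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0)
    stop("'a' must be a single nonnegative age", call. = FALSE)
  a_min <- max(incidence_min_age(rates), 0)
  if (a <= a_min) return(0)                       # no diseased yet
  if (!is.null(rates$relative_mortality) &&
      is_constant_profile(rates$relative_mortality))
    return(rates$relative_mortality$default_value *
             eval_rate(rates$mortality_healthy, t, a))
  cache <- characteristic_cache(rates, t, a, settings)
  w <- cache$density                              # C(t, a, delta), cohort-normalised
  dmax <- a - a_min
  denom <- quad_split(w, 0, dmax, profile_breaks(rates, dmax), settings,
                      rule = simpson_total)
  if (denom <= 0) return(0)
  num_f <- function(delta) eval_m1(rates, rep_len(t, length(delta)),
                                   rep_len(a, length(delta)), delta) * w(delta)
  num <- quad_split(num_f, 0, dmax, profile_breaks(rates, dmax), settings,
                    rule = simpson_total)
  num / denom
}

# Shared per-(t, a) cache: cumulative hazards along the characteristic and
# the (unnormalised) duration density of prevalent cases,
#   C(t, a, delta) = i(t-delta, a-delta) * Mtilde(a-delta) * exp(-M1(t,a,delta)),
# where Mtilde(y) = exp(-int_{a_min}^{y} (m0 + i)).  The survival factor over
# [0, a_min] is common to every term of the prevalence ratio and cancels, so
# rates are never evaluated below the incidence domain.
characteristic_cache <- function(rates, t, a, settings) {
  a_min <- max(incidence_min_age(rates), 0)
  c_line <- t - a
  H01 <- cumulative_integral(outflow_on_characteristic(rates, c_line),
                             a_min, a, settings)
  if (!is.null(rates$relative_mortality)) {
    G <- cumulative_integral(m0_on_characteristic(rates, c_line),
                             a_min, a, settings)
    M1 <- function(delta) m1_cumhaz_profile(rates, a, delta, G)
  } else {
    M1 <- function(delta)
      vapply(delta, function(d) {
        if (d == 0) return(0)
        romberg_quad(function(tau) rates$mortality_diseased(
          t - d + tau, a - d + tau, tau), 0, d, settings)
      }, numeric(1))
  }
  density <- function(delta)
    eval_rate(rates$incidence, t - delta, a - delta) *
      exp(-H01(a - delta)) * exp(-M1(delta))
  list(a_min = a_min, H01 = H01, M1 = M1, density = density)
}

#' Age-specific prevalence via Keiding's integral formula
#'
#' Computes the prevalence \eqn{p(t, a) = C^*/(S + C^*)} of the chronic
#' disease from the model rates by integrating, over the disease duration
#' \eqn{\delta}, the density of subjects who contracted the disease at age
#' \eqn{a - \delta} and survived with it until age \eqn{a}:
#' \deqn{p(t,a) = \frac{\int_0^a i\, \mathcal{M}_{t,a}(a-\delta)\,
#'   e^{-M_1(t,a,\delta)}\, \mathrm{d}\delta}
#'   {\mathcal{M}_{t,a}(a) + \int_0^a i\, \mathcal{M}_{t,a}(a-\delta)\,
#'   e^{-M_1(t,a,\delta)}\, \mathrm{d}\delta},}
#' with \eqn{\mathcal{M}_{t,a}(y) = \exp(-\int_0^y m_0 + i)} evaluated along
#' the characteristic through `(t, a)`.  The birth-cohort size cancels in
#' the ratio, as does the survival factor below the incidence domain, so
#' only ages at and above the incidence minimum age are ever evaluated.
#'
#' @inheritParams cumulative_duration_hazard
#' @return A proportion in `[0, 1)`; 0 at and below the incidence
#'   minimum age.
#' @examples
#' rates <- dementia_rates()
#' prevalence_keiding(rates, t = to_model_time(rates, 2010), a = 80)
#' @export
prevalence_keiding <- function(rates, t, a, settings = quadrature_settings()) {
  stopifnot(inherits(rates, "illness_death_rates"))
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0)
    stop("'a' must be a single nonnegative age", call. = FALSE)
  a_min <- max(incidence_min_age(rates), 0)
  if (a <= a_min) return(0)
  cache <- characteristic_cache(rates, t, a, settings)
  dmax <- a - a_min
  num <- quad_split(cache$density, 0, dmax, profile_breaks(rates, dmax),
                    settings, rule = simpson_total)
  healthy <- exp(-attr(cache$H01, "total"))       # Mtilde(a)
  if (healthy == 0)
    stop_numerical(sprintf(
      "healthy survival underflowed at (t = %g, a = %g); prevalence degenerates to 1",
      t, a))
  num / (healthy + num)
}

#' Prevalence on a (time x age) grid
#'
#' Evaluates [prevalence_keiding()] on the Cartesian grid of `time_points`
#' and `ages`.
#'
#' @param rates An [illness_death_rates()].
#' @param time_points Calendar times (years since the time origin).
#' @param ages Ages in years, ascending.
#' @param settings A [quadrature_settings()].
#' @return An object of class `prevalence_surface`: list with `time_points`,
#'   `ages` and the `values` matrix (rows = time points).
#' @export
prevalence_surface <- function(rates, time_points, ages,
                               settings = quadrature_settings()) {
  stopifnot(inherits(rates, "illness_death_rates"),
            is.numeric(time_points), length(time_points) >= 1L,
            is.numeric(ages), length(ages) >= 1L)
  if (is.unsorted(ages, strictly = TRUE))
    stop("'ages' must be strictly ascending", call. = FALSE)
  vals <- matrix(NA_real_, nrow = length(time_points), ncol = length(ages))
  for (ti in seq_along(time_points))
    for (ai in seq_along(ages))
      vals[ti, ai] <- tryCatch(
        prevalence_keiding(rates, time_points[ti], ages[ai], settings),
        error = function(e) stop(sprintf("at (t = %g, a = %g): %s",
                                         time_points[ti], ages[ai],
                                         conditionMessage(e)), call. = FALSE))
  structure(list(time_points = time_points, ages = ages, values = vals),
            class = "prevalence_surface")
}

#' @export
print.prevalence_surface <- function(x, ...) {
  cat(sprintf("Prevalence surface: %d time point(s) x %d age(s)\n",
              length(x$time_points), length(x$ages)))
  print(utils::head(as.data.frame(x), 10))
  if (length(x$time_points) * length(x$ages) > 10) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.prevalence_surface <- function(x, ...) {
  data.frame(time = rep(x$time_points, each = length(x$ages)),
             age = rep(x$ages, times = length(x$time_points)),
             prevalence = as.vector(t(x$values)))
}

#' Write a prevalence surface to CSV
#'
#' Long format with header `time,age,prevalence`, plain decimal notation.
#'
#' @param surface A [prevalence_surface()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prevalence_surface <- function(surface, path) {
  stopifnot(inherits(surface, "prevalence_surface"))
  df <- as.data.frame(surface)
  df$prevalence <- format(df$prevalence, digits = 15, scientific = FALSE,
                          trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
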