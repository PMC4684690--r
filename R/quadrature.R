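#' Quadrature accuracy settings
#'
#' Controls the Romberg integration used throughout the forward model.
#' Integration stops once the Richardson-extrapolated estimate changes by
#' less than `max(absolute_tolerance, relative_tolerance * |value|)` between
#' refinement levels; failure to converge within `max_refinements` interval
#' halvings raises a numerical-failure error that carries the achieved
#' estimate.
#'
#' @param relative_tolerance Relative accuracy goal (dimensionless).
#' @param absolute_tolerance Absolute accuracy floor, used where the integral
#'   is close to 0.
#' @param max_refinements Maximum number of interval halvings (`>= 4`).
#' @return An object of class `quadrature_settings`.
#' @export
quadrature_settings <- function(relative_tolerance = 1e-8,
                                absolute_tolerance = 1e-12,
                                max_refinements = 18L) {
  stopifnot(is.numeric(relative_tolerance), relative_tolerance > 0,
            is.numeric(absolute_tolerance), absolute_tolerance > 0,
            is.numeric(max_refinements), max_refinements >= 4)
  structure(
    list(relative_tolerance = relative_tolerance,
         absolute_tolerance = absolute_tolerance,
         max_refinements = as.integer(max_refinements)),
    class = "quadrature_settings")
}

#' Raise a numerical-failure error carrying the achieved estimate
#' @noRd
stop_numerical <- function(msg, estimate = NA_real_, error = NA_real_) {
  cond <- structure(
    class = c("illnessdeath_numerical_failure", "error", "condition"),
    list(message = msg, call = sys.call(-1),
         estimate = estimate, error = error))
  stop(cond)
}

#' Romberg quadrature of a vectorised integrand
#'
#' Classic Romberg scheme: trapezoidal refinements accelerated by Richardson
#' extrapolation.  `f` must accept a numeric vector and return one.  Smooth
#' integrands (the model's hazards are exponentials) converge in a handful
#' of levels to the prescribed accuracy.
#'
#' @param f Vectorised integrand.
#' @param lower,upper Integration limits, `lower <= upper`.
#' @param settings A [quadrature_settings()].
#' @return The integral estimate (scalar).
#' @noRd
romberg_quad <- function(f, lower, upper, settings = quadrature_settings()) {
  if (upper < lower) stop("'upper' must be >= 'lower'", call. = FALSE)
  if (upper == lower) return(0)
  jmax <- 10L                          # deeper columns only amplify roundoff
  h <- upper - lower
  prev_row <- h / 2 * sum(f(c(lower, upper)))
  prev_diag <- prev_row[1L]
  err <- Inf
  for (k in seq_len(settings$max_refinements)) {
    h <- h / 2
    new_x <- lower + h * seq(1, by = 2, length.out = 2^(k - 1))
    ncol <- min(k, jmax)
    row <- numeric(ncol + 1L)
    row[1L] <- prev_row[1L] / 2 + h * sum(f(new_x))
    for (j in seq_len(ncol)) {
      fac <- 4^j
      row[j + 1L] <- (fac * row[j] - prev_row[j]) / (fac - 1)
    }
    diag <- row[ncol + 1L]
    if (k >= 3L) {                     # require a minimally resolved tableau
      err <- abs(diag - prev_diag)
      tol <- max(settings$absolute_tolerance,
                 settings$relative_tolerance * abs(diag))
      if (err <= tol) return(diag)
    }
    prev_row <- row
    prev_diag <- diag
  }
  stop_numerical(
    sprintf("Romberg quadrature did not reach the prescribed accuracy on [%g, %g]",
            lower, upper),
    estimate = prev_diag, error = err)
}

#' Composite-Simpson integral with interval doubling
#'
#' Doubles the number of panels until two successive estimates agree to the
#' prescribed accuracy.  Used instead of Romberg for integrands that are
#' only piecewise-smooth in higher derivatives (those built from the cached
#' cumulative-hazard interpolants), where Richardson extrapolation gains
#' nothing and can stall.
#' @noRd
simpson_total <- function(f, lower, upper, settings = quadrature_settings()) {
  if (upper < lower) stop("'upper' must be >= 'lower'", call. = FALSE)
  if (upper == lower) return(0)
  simpson_n <- function(n) {
    x <- seq(lower, upper, length.out = 2L * n + 1L)
    h <- (upper - lower) / (2 * n)
    w <- rep(c(4, 2), n); w[2L * n] <- 1
    h / 3 * sum(c(1, w) * f(x))
  }
  n <- 16L
  prev <- simpson_n(n)
  for (k in seq_len(settings$max_refinements)) {
    n <- 2L * n
    cur <- simpson_n(n)
    if (abs(cur - prev) <= max(settings$absolute_tolerance,
                               settings$relative_tolerance * abs(cur)))
      return(cur)
    prev <- cur
  }
  stop_numerical(
    sprintf("Simpson quadrature did not reach the prescribed accuracy on [%g, %g]",
            lower, upper),
    estimate = prev)
}

#' Cumulative integral of a nonnegative vectorised integrand
#'
#' Returns a function \eqn{H(y) = \int_{lower}^{y} f(x)\,dx} valid on
#' `[lower, upper]`, built by composite Simpson panels on a grid that is
#' refined (doubled) until two successive resolutions agree to the
#' prescribed accuracy, then interpolated by a monotone Hermite spline.
#' This is the shared-grid cache used for the inner cumulative hazards of
#' the prevalence integral.
#'
#' @return A vectorised function of `y`; attribute `"total"` holds
#'   `H(upper)`.
#' @noRd
cumulative_integral <- function(f, lower, upper,
                                settings = quadrature_settings()) {
  if (upper < lower) stop("'upper' must be >= 'lower'", call. = FALSE)
  if (upper == lower) {
    g <- function(y) rep_len(0, length(y))
    attr(g, "total") <- 0
    return(g)
  }
  simpson_cum <- function(n) {         # n panels of 2 subintervals each
    x <- seq(lower, upper, length.out = 2L * n + 1L)
    fx <- f(x)
    h <- (upper - lower) / (2 * n)
    i0 <- seq(1L, 2L * n - 1L, by = 2L)
    panels <- h / 3 * (fx[i0] + 4 * fx[i0 + 1L] + fx[i0 + 2L])
    list(x = x[seq(1L, 2L * n + 1L, by = 2L)], H = c(0, cumsum(panels)))
  }
  n <- 32L
  prev <- simpson_cum(n)
  sp_prev <- stats::splinefun(prev$x, prev$H, method = "monoH.FC")
  for (k in seq_len(settings$max_refinements)) {
    n <- 2L * n
    cur <- simpson_cum(n)
    sp_cur <- stats::splinefun(cur$x, cur$H, method = "monoH.FC")
    # compare the interpolants where they disagree most: the fine nodes and
    # the fine-interval midpoints (controls the spline error, not just the
    # Simpson node error)
    probe <- seq(lower, upper, length.out = 4L * n + 1L)
    err <- max(abs(sp_cur(probe) - sp_prev(probe)))
    scale <- max(abs(cur$H), settings$absolute_tolerance)
    if (err <= max(settings$absolute_tolerance,
                   0.1 * settings$relative_tolerance * scale) ||
        n >= 65536L) {
      g <- function(y) sp_cur(pmin(pmax(y, lower), upper))
      attr(g, "total") <- cur$H[length(cur$H)]
      return(g)
    }
    prev <- cur
    sp_prev <- sp_cur
  }
  stop_numerical("cumulative integral did not reach the prescribed accuracy",
                 estimate = prev$H[length(prev$H)])
}
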