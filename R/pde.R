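#' Characteristic-line solver settings
#'
#' The prevalence PDE involves only the directional derivative
#' \eqn{(\partial_t + \partial_a) p}, so along a characteristic line
#' \eqn{t - a = \mathrm{const}} it is an ordinary differential equation in
#' age.  It is integrated with the classic fixed-step fourth-order
#' Runge-Kutta scheme from `start_age` (where \eqn{p = 0} is imposed) to the
#' target age; the step is shrunk, if necessary, to divide the integration
#' interval exactly.
#'
#' @param step_size Age step in years along the characteristic.
#' @param start_age Age at which \eqn{p = 0} is imposed.  `NULL` (default)
#'   means the incidence minimum age: below it no disease can occur, so the
#'   prevalence is identically 0 there and any earlier start yields the
#'   same solution.
#' @param m1_star_grid_step Age spacing (years) of the grid on which the
#'   duration-averaged mortality \eqn{m_1^*} is precomputed and then
#'   interpolated when the diseased mortality depends on duration.
#' @return An object of class `characteristic_settings`.
#' @export
characteristic_settings <- function(step_size = 0.05, start_age = NULL,
                                    m1_star_grid_step = 0.5) {
  stopifnot(is.numeric(step_size), length(step_size) == 1L, step_size > 0,
            is.null(start_age) || (is.numeric(start_age) && start_age >= 0),
            is.numeric(m1_star_grid_step), m1_star_grid_step > 0)
  structure(list(step_size = step_size, start_age = start_age,
                 method = "rk4", m1_star_grid_step = m1_star_grid_step),
            class = "characteristic_settings")
}

# age nodes from start to target with a step that divides the interval
characteristic_nodes <- function(start, target, step) {
  n <- max(1L, ceiling((target - start) / step - 1e-9))
  seq(start, target, length.out = n + 1L)
}

# run deSolve's fixed-step RK4 for dp/da = rhs(x, p) and return p(target)
integrate_characteristic <- function(rhs, start, target, step) {
  if (target <= start) return(0)
  times <- characteristic_nodes(start, target, step)
  sol <- deSolve::ode(y = c(p = 0), times = times,
                      func = function(x, y, parms) list(rhs(x, y[[1L]])),
                      parms = NULL, method = "rk4")
  p <- sol[, "p"]
  tol <- 100 * .Machine$double.eps + step^4
  if (any(p < -tol) || any(p > 1 + tol))
    stop_numerical(sprintf(
      "prevalence left [0, 1] along the characteristic (range %.3g..%.3g)",
      min(p), max(p)), estimate = p[length(p)])
  min(max(p[length(p)], 0), 1)
}

#' Age-specific prevalence by integrating the prevalence PDE
#'
#' Solves the initial-value problem
#' \deqn{(\partial_t + \partial_a)\, p = (1 - p)\,\big(i - p\,(m_1^* - m_0)\big),
#'   \qquad p(t, 0) = 0,}
#' along the characteristic through `(t, a)`.  When the diseased mortality
#' is duration-independent (a constant relative-mortality profile),
#' \eqn{m_1^* = m_1} exactly and is evaluated directly; otherwise
#' \eqn{m_1^*} is obtained from the closed-form duration density (see
#' [m1_star()]) on an age grid along the characteristic and interpolated at
#' the Runge-Kutta nodes.
#'
#' @param rates An [illness_death_rates()].
#' @param t Calendar time, years since the time origin.
#' @param a Age in years, at least the solver's start age.
#' @param settings A [characteristic_settings()].
#' @param quadrature A [quadrature_settings()], used only when \eqn{m_1^*}
#'   must be computed from the duration density.
#' @return A proportion in `[0, 1)`.
#' @seealso [prevalence_keiding()] for the equivalent integral formula.
#' @export
solve_prevalence_pde <- function(rates, t, a,
                                 settings = characteristic_settings(),
                                 quadrature = quadrature_settings()) {
  stopifnot(inherits(rates, "illness_death_rates"),
            inherits(settings, "characteristic_settings"))
  start <- if (is.null(settings$start_age))
    max(incidence_min_age(rates), 0) else settings$start_age
  if (a < start)
    stop("'a' must be at least the start age ", start, call. = FALSE)
  # below the incidence minimum age the solution is identically 0, so the
  # integration may begin there: this keeps Runge-Kutta stages away from the
  # switch-on discontinuity of the incidence and makes the result exactly
  # independent of any earlier start age
  start <- min(max(start, incidence_min_age(rates)), a)
  if (a <= start) return(0)
  c_line <- t - a
  duration_free <- !is.null(rates$relative_mortality) &&
    is_constant_profile(rates$relative_mortality)
  if (duration_free) {
    R <- rates$relative_mortality$default_value
    m1s <- function(x) R * eval_rate(rates$mortality_healthy, c_line + x, x)
  } else {
    grid <- characteristic_nodes(start, a,
                                 settings$m1_star_grid_step)
    vals <- vapply(grid, function(x) m1_star(rates, c_line + x, x, quadrature),
                   numeric(1))
    # where the diseased pool is still empty m1* is 0 by definition; use the
    # newest-case limit m1(t, a, 0) instead so the interpolant does not
    # overshoot at the onset boundary (p = 0 there, so the solution is
    # unaffected by the substitution)
    empty <- vals == 0
    if (any(empty))
      vals[empty] <- eval_m1(rates, c_line + grid[empty], grid[empty],
                             rep_len(0, sum(empty)))
    m1s <- if (length(grid) > 1L)
      stats::splinefun(grid, vals, method = "fmm") else function(x) vals
  }
  rhs <- function(x, p) {
    i <- eval_rate(rates$incidence, c_line + x, x)
    m0 <- eval_rate(rates$mortality_healthy, c_line + x, x)
    (1 - p) * (i - p * (m1s(x) - m0))
  }
  integrate_characteristic(rhs, start, a, settings$step_size)
}

#' Prevalence from general mortality and relative mortality
#'
#' Solves the prevalence PDE in the parameterisation used when only the
#' whole-population mortality \eqn{m(t, a)} and the relative mortality
#' \eqn{R(t, a)} are known:
#' \deqn{(\partial_t + \partial_a)\, p = (1 - p)\,\Big(i -
#'   m\,\frac{p (R - 1)}{p (R - 1) + 1}\Big),}
#' where the fraction is the population attributable fraction of mortality
#' (see [attributable_fraction()]).
#'
#' @param rates A [general_mortality_rates()].
#' @inheritParams solve_prevalence_pde
#' @return A proportion in `[0, 1)`.
#' @export
solve_prevalence_general <- function(rates, t, a,
                                     settings = characteristic_settings()) {
  stopifnot(inherits(rates, "general_mortality_rates"),
            inherits(settings, "characteristic_settings"))
  start <- if (is.null(settings$start_age))
    max(incidence_min_age(rates), 0) else settings$start_age
  if (a < start)
    stop("'a' must be at least the start age ", start, call. = FALSE)
  start <- min(max(start, incidence_min_age(rates)), a)
  c_line <- t - a
  rhs <- function(x, p) {
    i <- eval_rate(rates$incidence, c_line + x, x)
    m <- eval_rate(rates$general_mortality, c_line + x, x)
    R <- rates$relative_mortality(c_line + x, x)
    (1 - p) * (i - m * attributable_fraction(p, R))
  }
  integrate_characteristic(rhs, start, a, settings$step_size)
}

#' Population attributable fraction of mortality
#'
#' The share of overall mortality attributable to the disease,
#' \deqn{\mathrm{PAF} = \frac{p (R - 1)}{p (R - 1) + 1},}
#' for prevalence \eqn{p} and relative mortality \eqn{R}.  Vectorised.
#'
#' @param p Prevalence proportion(s) in `[0, 1]`.
#' @param R Relative mortality (ies), `> 0`.
#' @return Attributable fraction(s); 0 when `p = 0` or `R = 1`, in `[0, 1)`
#'   for `R >= 1`.
#' @export
attributable_fraction <- function(p, R) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("'p' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(R) || anyNA(R) || any(R <= 0))
    stop("'R' must be positive", call. = FALSE)
  p * (R - 1) / (p * (R - 1) + 1)
}
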