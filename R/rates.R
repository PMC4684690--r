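#' Log-linear hazard rate
#'
#' Constructs a hazard of the Gompertz type with a log-linear calendar-time
#' trend,
#' \deqn{\lambda(t, a) = \exp(\beta_0 + \beta_a a + \beta_t t),}
#' where \eqn{a} is age in years and \eqn{t} is calendar time in years since
#' the model's time origin.  Below `min_age` the hazard is identically 0,
#' which is how an incidence rate that only operates from a given age onwards
#' (e.g. dementia from age 50) is represented.
#'
#' @param beta0 Intercept on the log-hazard scale (dimensionless).
#' @param beta_age Slope per year of age.
#' @param beta_time Slope per calendar year; use `-log(1.01)` for a secular
#'   1\% annual decline.
#' @param min_age Age in years below which the rate is 0.  Default `-Inf`
#'   (no restriction).
#' @return An object of class `parametric_rate`.
#' @examples
#' # dementia incidence in German males: i(a) = exp(-12.8 + 0.11 a), a >= 50
#' inc <- parametric_rate(-12.8, 0.11, 0, min_age = 50)
#' eval_rate(inc, t = 50, a = 62.5)
#' @seealso [eval_rate()], [illness_death_rates()]
#' @export
parametric_rate <- function(beta0, beta_age = 0, beta_time = 0, min_age = -Inf) {
  for (nm in c("beta0", "beta_age", "beta_time")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  if (!is.numeric(min_age) || length(min_age) != 1L || is.na(min_age))
    stop("'min_age' must be a single number (possibly -Inf)", call. = FALSE)
  structure(
    list(beta0 = beta0, beta_age = beta_age, beta_time = beta_time,
         min_age = min_age),
    class = "parametric_rate")
}

#' @export
print.parametric_rate <- function(x, ...) {
  cat(sprintf("Log-linear hazard: exp(%g%+g*a%+g*t)", x$beta0, x$beta_age,
              x$beta_time))
  if (is.finite(x$min_age)) cat(sprintf("  [0 for a < %g]", x$min_age))
  cat("\n")
  invisible(x)
}

#' Evaluate a hazard rate
#'
#' Evaluates a rate object at calendar time `t` (years since the model
#' origin) and age `a` (years).  Vectorised over `t` and `a`.
#'
#' @param rate A `parametric_rate`, or a plain function of `(t, a)`.
#' @param t Calendar time in years since the time origin.
#' @param a Age in years.
#' @return Hazard per person-year (numeric, same length as `t`/`a`).
#' @export
eval_rate <- function(rate, t, a) {
  if (!is.numeric(t) || !is.numeric(a) || anyNA(t) || anyNA(a) ||
      any(!is.finite(t)) || any(!is.finite(a)))
    stop("'t' and 'a' must be finite numerics", call. = FALSE)
  if (is.function(rate)) return(rate(t, a))
  if (!inherits(rate, "parametric_rate"))
    stop("'rate' must be a parametric_rate or a function(t, a)", call. = FALSE)
  out <- exp(rate$beta0 + rate$beta_age * a + rate$beta_time * t)
  out[a < rate$min_age] <- 0
  out
}

#' Piecewise-constant relative-mortality profile
#'
#' Represents the relative mortality \eqn{R(d)} of diseased versus healthy
#' subjects as a right-continuous piecewise-constant function of disease
#' duration \eqn{d} (years since onset).  `values[k]` applies on
#' `[c(0, breakpoints)[k], breakpoints[k])`; beyond the last breakpoint
#' `default_value` applies.  With no breakpoints the profile is the constant
#' `default_value`, i.e. a duration-independent relative mortality.
#'
#' @param breakpoints Strictly increasing durations in years (may be empty).
#' @param values Multipliers, one per interval before each breakpoint.
#' @param default_value Multiplier beyond the last breakpoint (or everywhere,
#'   if there are no breakpoints).
#' @return An object of class `duration_profile`.
#' @examples
#' duration_profile(default_value = 2.63)          # constant R = 2.63
#' duration_profile(c(1, 2), c(3, 2), 1)           # step profile
#' @export
duration_profile <- function(breakpoints = numeric(), values = numeric(),
                             default_value) {
  breakpoints <- as.numeric(breakpoints)
  values <- as.numeric(values)
  if (length(breakpoints) != length(values))
    stop("'breakpoints' and 'values' must have equal length", call. = FALSE)
  if (length(breakpoints) &&
      (any(breakpoints < 0) || any(diff(breakpoints) <= 0) ||
       breakpoints[1L] < 0))
    stop("'breakpoints' must be nonnegative and strictly increasing",
         call. = FALSE)
  if (!is.numeric(default_value) || length(default_value) != 1L ||
      !is.finite(default_value) || default_value <= 0)
    stop("'default_value' must be a single positive number", call. = FALSE)
  if (length(values) && any(!is.finite(values) | values <= 0))
    stop("all 'values' must be positive and finite", call. = FALSE)
  structure(
    list(breakpoints = breakpoints, values = values,
         default_value = default_value),
    class = "duration_profile")
}

#' @export
print.duration_profile <- function(x, ...) {
  if (!length(x$breakpoints)) {
    cat(sprintf("Constant relative mortality R = %g\n", x$default_value))
  } else {
    lo <- c(0, x$breakpoints)
    cat("Piecewise-constant relative mortality R(d):\n")
    for (k in seq_along(x$breakpoints))
      cat(sprintf("  [%g, %g): %g\n", lo[k], x$breakpoints[k], x$values[k]))
    cat(sprintf("  [%g, Inf): %g\n", x$breakpoints[length(x$breakpoints)],
                x$default_value))
  }
  invisible(x)
}

#' Evaluate a duration profile
#'
#' Right-continuous piecewise-constant lookup of the relative mortality at
#' disease duration `d`.  Vectorised over `d`.
#'
#' @param profile A [duration_profile()].
#' @param d Duration in years since disease onset; must be `>= 0`.
#' @return Relative-mortality multiplier(s).
#' @export
eval_duration_profile <- function(profile, d) {
  stopifnot(inherits(profile, "duration_profile"))
  if (!is.numeric(d) || anyNA(d) || any(d < 0))
    stop("'d' must be nonnegative", call. = FALSE)
  if (!length(profile$breakpoints))
    return(rep_len(profile$default_value, length(d)))
  vals <- c(profile$values, profile$default_value)
  # interval index: d < breakpoints[1] -> 1, ..., d >= last -> length+1
  idx <- findInterval(d, profile$breakpoints, left.open = FALSE) + 1L
  vals[idx]
}

#' Is a profile duration-independent?
#' @noRd
is_constant_profile <- function(profile) {
  inherits(profile, "duration_profile") && length(profile$breakpoints) == 0L
}

#' Rate bundle for the three-state illness-death model
#'
#' Bundles the transition rates of the irreversible illness-death model
#' (healthy \eqn{\to} diseased \eqn{\to} dead, healthy \eqn{\to} dead): the
#' incidence \eqn{i(t, a)}, the mortality \eqn{m_0(t, a)} of the healthy,
#' and the mortality \eqn{m_1(t, a, d)} of the diseased, where \eqn{d} is
#' the disease duration.  `m1` is given either as a [duration_profile()]
#' `R(d)` acting multiplicatively on `m0` (so
#' \eqn{m_1(t,a,d) = R(d)\, m_0(t,a)}), or as an arbitrary function
#' `function(t, a, d)`.
#'
#' All internal calendar times are measured in years since `time_origin`;
#' user-facing functions that accept calendar years convert via
#' [to_model_time()].
#'
#' @param incidence Incidence rate: a [parametric_rate()] or `function(t, a)`.
#' @param mortality_healthy Mortality of the healthy: a [parametric_rate()]
#'   or `function(t, a)`.
#' @param relative_mortality A [duration_profile()], or a single positive
#'   number (shorthand for a constant profile).  Mutually exclusive with
#'   `mortality_diseased`.
#' @param mortality_diseased An arbitrary diseased-mortality hazard
#'   `function(t, a, d)`.  Mutually exclusive with `relative_mortality`.
#' @param time_origin Calendar year mapped to \eqn{t = 0}.
#' @return An object of class `illness_death_rates`.
#' @examples
#' rates <- illness_death_rates(
#'   incidence         = parametric_rate(-12.8, 0.11, 0, min_age = 50),
#'   mortality_healthy = parametric_rate(-9.0, 0.085, -log(1.01)),
#'   relative_mortality = 2.63,
#'   time_origin = 1960)
#' eval_m1(rates, t = 50, a = 80, d = 3)   # 2.63 * m0(50, 80)
#' @export
illness_death_rates <- function(incidence, mortality_healthy,
                                relative_mortality = NULL,
                                mortality_diseased = NULL,
                                time_origin = 0) {
  if (is.null(relative_mortality) == is.null(mortality_diseased))
    stop("give exactly one of 'relative_mortality' or 'mortality_diseased'",
         call. = FALSE)
  if (!is.null(relative_mortality)) {
    if (is.numeric(relative_mortality) && length(relative_mortality) == 1L)
      relative_mortality <- duration_profile(default_value = relative_mortality)
    stopifnot(inherits(relative_mortality, "duration_profile"))
  } else if (!is.function(mortality_diseased)) {
    stop("'mortality_diseased' must be a function(t, a, d)", call. = FALSE)
  }
  for (nm in c("incidence", "mortality_healthy")) {
    v <- get(nm)
    if (!inherits(v, "parametric_rate") && !is.function(v))
      stop(sprintf("'%s' must be a parametric_rate or a function(t, a)", nm),
           call. = FALSE)
  }
  stopifnot(is.numeric(time_origin), length(time_origin) == 1L,
            is.finite(time_origin))
  structure(
    list(incidence = incidence, mortality_healthy = mortality_healthy,
         relative_mortality = relative_mortality,
         mortality_diseased = mortality_diseased,
         time_origin = time_origin),
    class = "illness_death_rates")
}

#' @export
print.illness_death_rates <- function(x, ...) {
  cat("Illness-death model rates (t = years since", x$time_origin, ")\n")
  cat("incidence i:          ")
  if (is.function(x$incidence)) cat("<function(t, a)>\n") else print(x$incidence)
  cat("healthy mortality m0: ")
  if (is.function(x$mortality_healthy)) cat("<function(t, a)>\n")
  else print(x$mortality_healthy)
  if (!is.null(x$relative_mortality)) {
    cat("diseased mortality m1 = R(d) * m0;  ")
    print(x$relative_mortality)
  } else {
    cat("diseased mortality m1: <function(t, a, d)>\n")
  }
  invisible(x)
}

#' Minimal age at which incidence can be positive
#' @noRd
incidence_min_age <- function(rates) {
  inc <- rates$incidence
  if (inherits(inc, "parametric_rate") && is.finite(inc$min_age))
    inc$min_age else 0
}

#' Convert calendar years to model time
#'
#' @param rates An [illness_death_rates()] (or anything with a `time_origin`
#'   field).
#' @param year Calendar year(s).
#' @return Years since the model's time origin.
#' @export
to_model_time <- function(rates, year) year - rates$time_origin

#' Evaluate the diseased mortality m1(t, a, d)
#'
#' In the relative-mortality representation this is
#' \eqn{R(d)\, m_0(t, a)}; an arbitrary-function representation is evaluated
#' directly.  Disease onset cannot precede birth, so `d <= a` is required.
#'
#' @param rates An [illness_death_rates()].
#' @param t Calendar time, years since the time origin.
#' @param a Age in years.
#' @param d Disease duration in years, `0 <= d <= a`.
#' @return Hazard per person-year.
#' @export
eval_m1 <- function(rates, t, a, d) {
  stopifnot(inherits(rates, "illness_death_rates"))
  if (!is.numeric(d) || anyNA(d) || any(d < 0))
    stop("'d' must be nonnegative", call. = FALSE)
  if (any(d > a))
    stop("duration 'd' cannot exceed age 'a'", call. = FALSE)
  if (!is.null(rates$relative_mortality))
    eval_duration_profile(rates$relative_mortality, d) *
      eval_rate(rates$mortality_healthy, t, a)
  else
    rates$mortality_diseased(t, a, d)
}

#' General-mortality rate bundle
#'
#' Alternative parameterisation of the illness-death model used when the
#' mortalities of the healthy and the diseased are not known separately but
#' the \emph{general mortality} \eqn{m(t, a)} of the whole population (from
#' vital statistics or life tables) and the \emph{relative mortality}
#' \eqn{R = m_1^*/m_0} (from disease-specific surveys) are.  The prevalence
#' then solves a PDE in which the excess-mortality term is
#' \eqn{m \cdot \mathrm{PAF}} with the population attributable fraction
#' \eqn{\mathrm{PAF} = p(R-1)/(p(R-1)+1)}; see
#' [solve_prevalence_general()].
#'
#' @param incidence Incidence rate: [parametric_rate()] or `function(t, a)`.
#' @param general_mortality Whole-population mortality: [parametric_rate()]
#'   or `function(t, a)`.
#' @param relative_mortality A single positive number, or a `function(t, a)`
#'   returning \eqn{R > 0}.
#' @param time_origin Calendar year mapped to \eqn{t = 0}.
#' @return An object of class `general_mortality_rates`.
#' @export
general_mortality_rates <- function(incidence, general_mortality,
                                    relative_mortality, time_origin = 0) {
  for (nm in c("incidence", "general_mortality")) {
    v <- get(nm)
    if (!inherits(v, "parametric_rate") && !is.function(v))
      stop(sprintf("'%s' must be a parametric_rate or a function(t, a)", nm),
           call. = FALSE)
  }
  if (is.numeric(relative_mortality)) {
    stopifnot(length(relative_mortality) == 1L,
              is.finite(relative_mortality), relative_mortality > 0)
    Rconst <- relative_mortality
    relative_mortality <- function(t, a) rep_len(Rconst, max(length(t), length(a)))
  } else if (!is.function(relative_mortality)) {
    stop("'relative_mortality' must be a constant or a function(t, a)",
         call. = FALSE)
  }
  stopifnot(is.numeric(time_origin), length(time_origin) == 1L,
            is.finite(time_origin))
  structure(
    list(incidence = incidence, general_mortality = general_mortality,
         relative_mortality = relative_mortality, time_origin = time_origin),
    class = "general_mortality_rates")
}

#' Read an illness-death rate configuration file
#'
#' Reads a YAML (or JSON, which YAML supersets) configuration with blocks
#' `incidence`, `mortality_healthy`, `relative_mortality` and `time_origin`
#' into an [illness_death_rates()] object.  Rate blocks carry the log-linear
#' coefficients `beta0`, `beta_age`, `beta_time` and optionally `min_age`;
#' the relative-mortality block is either `{constant: x}` or
#' `{breakpoints: [...], values: [...], default: x}`.
#'
#' The packaged configuration of the German dementia example is available
#' via `system.file("extdata", "dementia_germany.yaml", package =
#' "illnessdeath")`.
#'
#' @param path Path to the configuration file.
#' @return An [illness_death_rates()] object.
#' @export
read_rates_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- c("incidence", "mortality_healthy", "relative_mortality")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config is missing block(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  as_rate <- function(b, what) {
    if (is.null(b$beta0)) stop("block '", what, "' needs 'beta0'", call. = FALSE)
    parametric_rate(b$beta0,
                    if (is.null(b$beta_age)) 0 else b$beta_age,
                    if (is.null(b$beta_time)) 0 else b$beta_time,
                    if (is.null(b$min_age)) -Inf else b$min_age)
  }
  rm <- cfg$relative_mortality
  profile <- if (!is.null(rm$constant)) {
    duration_profile(default_value = rm$constant)
  } else {
    duration_profile(unlist(rm$breakpoints), unlist(rm$values), rm$default)
  }
  illness_death_rates(
    incidence = as_rate(cfg$incidence, "incidence"),
    mortality_healthy = as_rate(cfg$mortality_healthy, "mortality_healthy"),
    relative_mortality = profile,
    time_origin = if (is.null(cfg$time_origin)) 0 else cfg$time_origin)
}
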