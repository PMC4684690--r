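#' Cross-sectional prevalence survey
#'
#' One cross-section: a survey time point together with age-specific
#' prevalence proportions on an age grid.
#'
#' @param survey_time Calendar time of the survey (years).
#' @param ages Ages in years, strictly increasing.
#' @param prevalence Prevalence proportions in `[0, 1)`, one per age.
#' @return An object of class `cross_section`.
#' @export
cross_section <- function(survey_time, ages, prevalence) {
  stopifnot(is.numeric(survey_time), length(survey_time) == 1L,
            is.finite(survey_time))
  ages <- as.numeric(ages); prevalence <- as.numeric(prevalence)
  if (length(ages) != length(prevalence))
    stop("'ages' and 'prevalence' must have equal length", call. = FALSE)
  if (is.unsorted(ages, strictly = TRUE))
    stop("'ages' must be strictly increasing", call. = FALSE)
  if (anyNA(prevalence) || any(prevalence < 0 | prevalence >= 1))
    stop("'prevalence' values must lie in [0, 1)", call. = FALSE)
  structure(list(survey_time = survey_time, ages = ages,
                 prevalence = prevalence),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("Cross-sectional prevalence survey at time %g (%d ages %g..%g)\n",
              x$survey_time, length(x$ages), min(x$ages), max(x$ages)))
  invisible(x)
}

#' Read a cross-section from CSV
#'
#' Expects a header row `age,prevalence`.
#'
#' @param path CSV file path.
#' @param survey_time Calendar time of the survey (years).
#' @return A [cross_section()].
#' @export
read_cross_section <- function(path, survey_time) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("age", "prevalence") %in% names(df)))
    stop("CSV must have columns 'age' and 'prevalence'", call. = FALSE)
  cross_section(survey_time, df$age, df$prevalence)
}

#' Write a cross-section to CSV (columns `age,prevalence`)
#' @param cs A [cross_section()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cross_section <- function(cs, path) {
  stopifnot(inherits(cs, "cross_section"))
  df <- data.frame(age = cs$ages,
                   prevalence = format(cs$prevalence, digits = 15,
                                       scientific = FALSE, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# prevalence of a cross-section at one age: exact grid match, or monotone
# cubic interpolation when allowed
cs_prevalence_at <- function(cs, age, interpolate, tol = 1e-8) {
  hit <- which(abs(cs$ages - age) <= tol)
  if (length(hit)) return(cs$prevalence[hit[1L]])
  if (!interpolate)
    stop(sprintf("age %g is not on the survey grid of time %g", age,
                 cs$survey_time), call. = FALSE)
  if (age < min(cs$ages) || age > max(cs$ages))
    stop(sprintf("age %g is outside the survey grid of time %g", age,
                 cs$survey_time), call. = FALSE)
  stats::splinefun(cs$ages, cs$prevalence, method = "monoH.FC")(age)
}

# common validation for the two finite-difference approximations
check_cs_pair <- function(cs0, cs1) {
  stopifnot(inherits(cs0, "cross_section"), inherits(cs1, "cross_section"))
  delta <- cs1$survey_time - cs0$survey_time
  if (!is.finite(delta) || delta <= 0)
    stop("the second survey must be later than the first", call. = FALSE)
  delta
}

#' Midpoint prevalence between two cross-sections
#'
#' Approximates the prevalence at the mid-survey time
#' \eqn{\tilde t = t_0 + \Delta/2} and age `a` by the mean of the two
#' observed values shifted half a lag along the cohort direction:
#' \deqn{p(\tilde t, a) \doteq \tfrac{1}{2}\big[p(t_0 + \Delta,\, a + \Delta/2)
#'   + p(t_0,\, a - \Delta/2)\big].}
#' Exact whenever \eqn{p} is linear in \eqn{(t, a)}.
#'
#' @param cs0,cs1 The earlier and later [cross_section()] surveys.
#' @param a Age in years.
#' @param interpolate Allow monotone cubic interpolation when
#'   `a - Delta/2` / `a + Delta/2` are not survey grid points (default
#'   `FALSE`: off-grid ages are an error).
#' @return A proportion.
#' @export
midpoint_prevalence <- function(cs0, cs1, a, interpolate = FALSE) {
  delta <- check_cs_pair(cs0, cs1)
  (cs_prevalence_at(cs1, a + delta / 2, interpolate) +
     cs_prevalence_at(cs0, a - delta / 2, interpolate)) / 2
}

#' Directional derivative of prevalence from two cross-sections
#'
#' Finite-difference approximation of \eqn{(\partial_t + \partial_a) p} at
#' the mid-survey time and age `a`:
#' \deqn{(\partial_t + \partial_a) p(\tilde t, a) \doteq
#'   \big[p(t_0 + \Delta,\, a + \Delta/2) - p(t_0,\, a - \Delta/2)\big] /
#'   \Delta.}
#' The difference is taken along the cohort direction, so it is exact for
#' prevalence surfaces linear in \eqn{(t, a)}.
#'
#' @inheritParams midpoint_prevalence
#' @return Rate of change per year.
#' @export
directional_derivative <- function(cs0, cs1, a, interpolate = FALSE) {
  delta <- check_cs_pair(cs0, cs1)
  (cs_prevalence_at(cs1, a + delta / 2, interpolate) -
     cs_prevalence_at(cs0, a - delta / 2, interpolate)) / delta
}

#' Estimate age-specific incidence from two cross-sections
#'
#' Inverts the prevalence PDE for the incidence rate,
#' \deqn{i = \frac{(\partial_t + \partial_a) p}{1 - p} +
#'   p\,(m_1^* - m_0),}
#' with the prevalence and its directional derivative approximated from the
#' two surveys (see [midpoint_prevalence()] and [directional_derivative()]).
#' Estimation requires the mortality of the healthy and the
#' duration-averaged mortality of the diseased at the mid-survey time; both
#' are supplied as functions of calendar time and age, in the same time
#' units as the surveys.
#'
#' Ages at which the estimate is produced are those `a` for which both
#' `a - Delta/2` and `a + Delta/2` lie on the respective survey grids (all
#' such interior ages are used).  Negative estimates are reported with a
#' warning rather than truncated: they flag inconsistent inputs.
#'
#' @param cs0,cs1 The earlier and later [cross_section()] surveys.
#' @param m0_fn Function `(t, a)` giving the mortality of the healthy.
#' @param m1_star_fn Function `(t, a)` giving the duration-averaged
#'   mortality of the diseased.
#' @param interpolate Allow monotone cubic interpolation of off-grid ages
#'   (default `FALSE`).
#' @param ages Ages at which to estimate; default (`NULL`) uses every age
#'   for which both shifted ages are on the survey grids.
#' @return An object of class `incidence_estimate` with fields
#'   `midpoint_time`, `ages`, `incidence`, `midpoint_prevalence`,
#'   `directional_derivative` and `negative` (logical flags).
#' @examples
#' spec <- experiment_spec()
#' css <- generate_cross_sections(spec)
#' rates <- spec$rates
#' m0_fn <- function(t, a) eval_rate(rates$mortality_healthy,
#'                                   to_model_time(rates, t), a)
#' est <- estimate_incidence(css[[1]], css[[2]], m0_fn,
#'                           function(t, a) 2.63 * m0_fn(t, a))
#' as.data.frame(est)
#' @export
estimate_incidence <- function(cs0, cs1, m0_fn, m1_star_fn,
                               interpolate = FALSE, ages = NULL) {
  delta <- check_cs_pair(cs0, cs1)
  stopifnot(is.function(m0_fn), is.function(m1_star_fn))
  t_mid <- cs0$survey_time + delta / 2
  if (is.null(ages)) {
    ages <- (cs0$ages + delta / 2)[
      vapply(cs0$ages + delta, function(x)
        any(abs(cs1$ages - x) <= 1e-8), logical(1))]
  }
  if (!length(ages))
    stop("no age has support on both survey grids", call. = FALSE)
  n <- length(ages)
  p_mid <- dd <- inc <- numeric(n)
  for (k in seq_len(n)) {
    p_mid[k] <- midpoint_prevalence(cs0, cs1, ages[k], interpolate)
    dd[k] <- directional_derivative(cs0, cs1, ages[k], interpolate)
    if (p_mid[k] >= 1)
      stop(sprintf("midpoint prevalence is 1 at age %g: incidence undefined",
                   ages[k]), call. = FALSE)
    inc[k] <- dd[k] / (1 - p_mid[k]) +
      p_mid[k] * (m1_star_fn(t_mid, ages[k]) - m0_fn(t_mid, ages[k]))
  }
  neg <- inc < 0
  if (any(neg))
    warning(sprintf("negative incidence estimate at age(s) %s; inputs may be inconsistent",
                    paste(ages[neg], collapse = ", ")), call. = FALSE)
  structure(list(midpoint_time = t_mid, ages = ages, incidence = inc,
                 midpoint_prevalence = p_mid, directional_derivative = dd,
                 negative = neg),
            class = "incidence_estimate")
}

#' @export
print.incidence_estimate <- function(x, ...) {
  cat(sprintf("Incidence estimated at mid-survey time %g (%d ages)\n",
              x$midpoint_time, length(x$ages)))
  print(as.data.frame(x), digits = 5)
  invisible(x)
}

#' @export
as.data.frame.incidence_estimate <- function(x, ...) {
  data.frame(age = x$ages, incidence = x$incidence,
             midpoint_prevalence = x$midpoint_prevalence,
             directional_derivative = x$directional_derivative)
}

#' Write an incidence estimate to CSV
#'
#' Columns `age,incidence,midpoint_prevalence,directional_derivative`.
#'
#' @param est An [estimate_incidence()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_incidence_estimate <- function(est, path) {
  stopifnot(inherits(est, "incidence_estimate"))
  utils::write.csv(as.data.frame(est), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Signed relative error in percent
#'
#' `100 * (estimate - truth) / truth`, the convention used to compare
#' estimated with true incidence rates.
#'
#' @param estimate,truth Numeric vectors (recycled); `truth` must be
#'   nonzero.
#' @return Signed percentages.
#' @export
relative_error <- function(estimate, truth) {
  if (!is.numeric(estimate) || !is.numeric(truth) || anyNA(truth))
    stop("'estimate' and 'truth' must be numeric", call. = FALSE)
  if (any(truth == 0))
    stop("'truth' must be nonzero", call. = FALSE)
  100 * (estimate - truth) / truth
}
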