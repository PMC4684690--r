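test_that("cumulative duration hazard matches closed forms and brute force", {
  expect_equal(cumulative_duration_hazard(dementia_rates(), 50, 80, 0), 0)
  const <- constant_rates(i = 0.01, m0 = 0.02, m1 = 0.07)
  expect_equal(cumulative_duration_hazard(const, 10, 60, 12.5), 0.07 * 12.5)
  # dementia rates, constant R: against a fine composite-Simpson oracle
  rates <- dementia_rates()
  for (case in list(c(t = 50, a = 80, d = 10), c(t = 55, a = 95, d = 30))) {
    oracle <- simpson_oracle(function(tau)
      2.63 * eval_rate(rates$mortality_healthy,
                       case[["t"]] - case[["d"]] + tau,
                       case[["a"]] - case[["d"]] + tau),
      0, case[["d"]])
    expect_equal(cumulative_duration_hazard(rates, case[["t"]], case[["a"]],
                                            case[["d"]]),
                 oracle, tolerance = 1e-8)
  }
  expect_error(cumulative_duration_hazard(rates, 50, 80, -1), "0 <= d <= a")
  expect_error(cumulative_duration_hazard(rates, 50, 80, 81), "0 <= d <= a")
})

test_that("healthy survival obeys closed forms and the quadrature oracle", {
  none <- constant_rates(i = 0, m0 = 0)
  expect_equal(survival_healthy(none, 5, 70), 1)
  const <- constant_rates(i = 0.004, m0 = 0.006)
  expect_equal(survival_healthy(const, 0, 50), exp(-0.01 * 50))
  rates <- dementia_rates()
  # oracle split at age 50, where the incidence switches on
  oracle <- exp(-(simpson_oracle(function(x)
    eval_rate(rates$mortality_healthy, 50 - 80 + x, x), 0, 50) +
      simpson_oracle(function(x)
        eval_rate(rates$mortality_healthy, 50 - 80 + x, x) +
          eval_rate(rates$incidence, 50 - 80 + x, x), 50, 80)))
  expect_equal(survival_healthy(rates, 50, 80), oracle, tolerance = 1e-8)
  expect_error(survival_healthy(rates, 50, -2), "nonnegative")
})

test_that("m1* reduces to R*m0 for constant profiles and is 0 in an empty pool", {
  rates <- dementia_rates()
  for (a in c(60, 75, 95))
    expect_equal(m1_star(rates, 50, a),
                 2.63 * eval_rate(rates$mortality_healthy, 50, a))
  expect_equal(m1_star(rates, 50, 50), 0)
  expect_equal(m1_star(rates, 50, 30), 0)
})

test_that("m1* with a step profile matches nested brute-force quadrature", {
  prof <- duration_profile(c(2, 5), c(4.0, 2.8), 1.9)
  rates <- dementia_rates(prof)
  t <- 50; a <- 70
  # oracle: duration density from first principles; every integral is split
  # at the profile breakpoints, where the integrands jump
  seg_simpson <- function(f, lower, upper, panels = 500L) {
    cuts <- sort(unique(c(lower, pmin(pmax(c(2, 5), lower), upper), upper)))
    sum(vapply(seq_len(length(cuts) - 1L), function(k) {
      eps <- (cuts[k + 1L] - cuts[k]) * 1e-12
      simpson_oracle(function(x) f(pmin(x, cuts[k + 1L] - eps)),
                     cuts[k], cuts[k + 1L], panels)
    }, numeric(1)))
  }
  dens <- function(delta) vapply(delta, function(d) {
    surv_h <- exp(-simpson_oracle(function(x)
      eval_rate(rates$mortality_healthy, t - a + x, x) +
        eval_rate(rates$incidence, t - a + x, x), 50, a - d, panels = 2000L))
    m1haz <- seg_simpson(function(tau)
      eval_duration_profile(prof, tau) *
        eval_rate(rates$mortality_healthy, t - d + tau, a - d + tau), 0, d)
    eval_rate(rates$incidence, t - d, a - d) * surv_h * exp(-m1haz)
  }, numeric(1))
  num <- seg_simpson(function(delta)
    eval_duration_profile(prof, delta) *
      eval_rate(rates$mortality_healthy, t, a) * dens(delta), 0, a - 50)
  den <- seg_simpson(dens, 0, a - 50)
  expect_equal(m1_star(rates, t, a), num / den, tolerance = 1e-6)
  # always between the extremes of m1 over the possible durations
  m0 <- eval_rate(rates$mortality_healthy, t, a)
  expect_gt(m1_star(rates, t, a), 1.9 * m0)
  expect_lt(m1_star(rates, t, a), 4.0 * m0)
})

test_that("prevalence is 0 without incidence and follows the constant-rate closed form", {
  no_inc <- constant_rates(i = 0, m0 = 0.01)
  expect_equal(prevalence_keiding(no_inc, 0, 40), 0)
  # m1 = m0 and constant i: dp/da = (1-p) i, so p = 1 - exp(-i a)
  bal <- constant_rates(i = 0.03, m0 = 0.01, m1 = 0.01)
  expect_equal(prevalence_keiding(bal, 0, 60), 1 - exp(-0.03 * 60),
               tolerance = 1e-7)
  # below / at the incidence minimum age
  expect_equal(prevalence_keiding(dementia_rates(), 50, 50), 0)
  expect_equal(prevalence_keiding(dementia_rates(), 50, 35), 0)
})

test_that("halving the tolerance moves prevalence by less than the prior tolerance", {
  rates <- dementia_rates()
  tol <- 1e-5
  p_prev <- prevalence_keiding(rates, 50, 90, quadrature_settings(tol))
  for (k in 1:3) {
    tol <- tol / 2
    p_next <- prevalence_keiding(rates, 50, 90, quadrature_settings(tol))
    expect_lt(abs(p_next - p_prev), 2 * tol)
    p_prev <- p_next
  }
})

test_that("hazards below the incidence minimum age cannot affect prevalence", {
  base <- dementia_rates()
  bumped <- illness_death_rates(
    incidence = base$incidence,
    mortality_healthy = function(t, a)
      eval_rate(base$mortality_healthy, t, a) + 0.5 * (a < 50),
    relative_mortality = 2.63,
    time_origin = 1960)
  for (a in c(60, 80, 100))
    expect_equal(prevalence_keiding(bumped, 50, a),
                 prevalence_keiding(base, 50, a), tolerance = 1e-10)
})

test_that("prevalence surfaces respect their invariants and round-trip CSV", {
  rates <- dementia_rates()
  surf <- prevalence_surface(rates, c(50, 55), c(50, seq(60, 100, by = 10)))
  expect_equal(dim(surf$values), c(2L, 6L))
  expect_true(all(surf$values >= 0 & surf$values < 1))
  expect_equal(surf$values[, 1L], c(0, 0))          # incidence starts at 50
  expect_true(all(diff(surf$values[1L, ]) > 0))     # increasing in age
  expect_true(all(diff(surf$values[2L, ]) > 0))
  one <- prevalence_surface(rates, 50, 80)
  expect_equal(one$values[1L, 1L], prevalence_keiding(rates, 50, 80))
  path <- tempfile(fileext = ".csv")
  write_prevalence_surface(surf, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("time", "age", "prevalence"))
  expect_equal(back$prevalence,
               as.vector(t(surf$values)), tolerance = 1e-10)
  expect_error(prevalence_surface(rates, 50, c(70, 60)), "ascending")
})
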