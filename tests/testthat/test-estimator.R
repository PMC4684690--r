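make_cs <- function(time, ages, p) cross_section(time, ages, p)

test_that("midpoint prevalence and directional derivative are the stated averages", {
  cs0 <- make_cs(2010, c(77.5, 80), c(0.1, 0.15))
  cs1 <- make_cs(2015, c(82.5, 85), c(0.2, 0.25))
  expect_equal(midpoint_prevalence(cs0, cs1, 80), (0.1 + 0.2) / 2)
  expect_equal(directional_derivative(cs0, cs1, 80), (0.2 - 0.1) / 5)
  zero0 <- make_cs(2010, 80, 0); zero1 <- make_cs(2015, 85, 0)
  expect_equal(midpoint_prevalence(zero0, zero1, 82.5), 0)
  same0 <- make_cs(2010, 80, 0.12); same1 <- make_cs(2015, 85, 0.12)
  expect_equal(directional_derivative(same0, same1, 82.5), 0)
  expect_error(midpoint_prevalence(cs0, cs1, 81), "not on the survey grid")
  expect_error(midpoint_prevalence(cs1, cs0, 80), "later")
})

test_that("both approximation steps are exact on surfaces linear in t + a", {
  # p(t, a) = alpha (t + a) + beta is constant in t - a direction's normal:
  # the cohort-direction average and difference are exact
  alpha <- 0.0008; beta <- -1.55
  p_lin <- function(t, a) alpha * (t + a) + beta
  ages <- seq(60, 100, by = 2.5)
  cs0 <- make_cs(2010, ages, p_lin(2010, ages))
  cs1 <- make_cs(2015, ages, p_lin(2015, ages))
  for (a in c(65, 80, 95)) {
    expect_equal(midpoint_prevalence(cs0, cs1, a), p_lin(2012.5, a))
    expect_equal(directional_derivative(cs0, cs1, a), 2 * alpha)
  }
})

test_that("incidence estimation implements the PDE inversion", {
  ages <- seq(60, 100, by = 2.5)
  # zero prevalence everywhere: both terms vanish
  z0 <- make_cs(2010, ages, rep(0, 17)); z1 <- make_cs(2015, ages, rep(0, 17))
  est <- estimate_incidence(z0, z1, function(t, a) 0.1, function(t, a) 0.3)
  expect_equal(est$incidence, rep(0, 15))
  expect_equal(est$ages, seq(62.5, 97.5, by = 2.5))
  expect_equal(est$midpoint_time, 2012.5)
  # no excess mortality: the estimate is the derivative term alone
  p0 <- seq(0.05, 0.21, by = 0.01); p1 <- p0 + 0.02
  cs0 <- make_cs(2010, ages, p0); cs1 <- make_cs(2015, ages, p1)
  m0_fn <- function(t, a) 0.02 + 0.0001 * a
  est2 <- estimate_incidence(cs0, cs1, m0_fn, m0_fn)
  k <- seq_along(est2$ages)
  expect_equal(est2$incidence,
               est2$directional_derivative / (1 - est2$midpoint_prevalence))
  expect_equal(est2$midpoint_prevalence, (p0[k] + p1[k + 2L]) / 2)
})

test_that("negative estimates are flagged, not clamped", {
  ages <- c(60, 62.5, 65, 67.5, 70)
  cs0 <- make_cs(2010, ages, c(0.30, 0.30, 0.30, 0.30, 0.30))
  cs1 <- make_cs(2015, ages, c(0.10, 0.10, 0.10, 0.10, 0.10))
  expect_warning(
    est <- estimate_incidence(cs0, cs1, function(t, a) 0.01,
                              function(t, a) 0.01),
    "negative")
  expect_true(all(est$incidence < 0))
  expect_true(all(est$negative))
})

test_that("estimates are equivariant under relabeling calendar years", {
  ages <- seq(60, 100, by = 2.5)
  p0 <- 0.002 * (ages - 58); p1 <- 0.0023 * (ages - 56)
  m0_fn <- function(t, a) exp(-9 + 0.085 * a - 0.01 * (t - 1960))
  m1_fn <- function(t, a) 2.63 * m0_fn(t, a)
  est <- estimate_incidence(make_cs(2010, ages, p0), make_cs(2015, ages, p1),
                            m0_fn, m1_fn)
  shift <- 37
  est_s <- estimate_incidence(make_cs(2010 + shift, ages, p0),
                              make_cs(2015 + shift, ages, p1),
                              function(t, a) m0_fn(t - shift, a),
                              function(t, a) m1_fn(t - shift, a))
  expect_equal(est_s$incidence, est$incidence)
  expect_equal(est_s$midpoint_time, est$midpoint_time + shift)
})

test_that("the midpoint approximation tracks the exact mid-survey prevalence", {
  spec <- experiment_spec()
  css <- generate_cross_sections(spec)
  p_hat <- midpoint_prevalence(css[[1L]], css[[2L]], 80)
  p_exact <- prevalence_keiding(spec$rates, to_model_time(spec$rates, 2012.5), 80)
  # cohort-direction curvature of p over the 5-year lag bounds the error
  expect_lt(abs(p_hat - p_exact), 2e-3)
})

test_that("off-grid ages interpolate only when explicitly allowed", {
  ages <- seq(60, 100, by = 2.5)
  p0 <- 0.001 * (ages - 55)^1.5
  cs0 <- make_cs(2010, ages, p0)
  cs1 <- make_cs(2014, ages, p0 * 1.1)   # lag 4: shifted ages fall off-grid
  expect_error(midpoint_prevalence(cs0, cs1, 80), "not on the survey grid")
  p_int <- midpoint_prevalence(cs0, cs1, 80, interpolate = TRUE)
  expect_gt(p_int, 0)
  expect_lt(abs(p_int - (0.001 * (78 - 55)^1.5 + 0.0011 * (82 - 55)^1.5) / 2),
            2e-4)
})

test_that("relative error is the signed percent deviation", {
  expect_equal(round(relative_error(0.0027006, 0.0026718), 2), 1.08)
  expect_equal(round(relative_error(0.0540997, 0.0550232), 2), -1.68)
  expect_equal(relative_error(0.42, 0.42), 0)
  expect_error(relative_error(1, 0), "nonzero")
})

test_that("cross-sections round-trip through CSV", {
  ages <- seq(60, 100, by = 2.5)
  cs <- make_cs(2010, ages, 0.001 * (ages - 55))
  path <- tempfile(fileext = ".csv")
  write_cross_section(cs, path)
  back <- read_cross_section(path, 2010)
  expect_equal(back$ages, cs$ages)
  expect_equal(back$prevalence, cs$prevalence, tolerance = 1e-12)
  expect_error(read_cross_section(tempfile(), 2010), "not found")
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_cross_section(bad, 2010), "columns")
})

test_that("cross-section validation rejects malformed surveys", {
  expect_error(cross_section(2010, c(60, 60), c(0.1, 0.2)), "increasing")
  expect_error(cross_section(2010, c(60, 65), c(0.1, 1)), "\\[0, 1\\)")
  expect_error(cross_section(2010, 60, c(0.1, 0.2)), "equal length")
})
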