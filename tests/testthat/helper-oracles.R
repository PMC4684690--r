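# Shared fixtures and independent numerical oracles used across the suite.

# Dementia-in-German-males benchmark table: true incidence exp(-12.8 + 0.11 a)
# and the study's published estimates with signed relative errors in percent.
dementia_table1 <- data.frame(
  age = seq(62.5, 97.5, by = 2.5),
  true_incidence = c(0.0026718, 0.0035175, 0.0046309, 0.0060967, 0.0080266,
                     0.0105672, 0.0139120, 0.0183156, 0.0241131, 0.0317456,
                     0.0417941, 0.0550232, 0.0724398, 0.0953692, 0.1255564),
  calculated_incidence = c(0.0027006, 0.0035542, 0.0046861, 0.0061226,
                           0.0080156, 0.0105659, 0.0138738, 0.0181919,
                           0.0238324, 0.0312618, 0.0411196, 0.0540997,
                           0.0712442, 0.0938397, 0.1238085),
  relative_error = c(1.08, 1.04, 1.19, 0.42, -0.14, -0.01, -0.28, -0.68,
                     -1.16, -1.52, -1.61, -1.68, -1.65, -1.60, -1.39))

# Composite Simpson rule on a fixed fine grid: brute-force quadrature oracle,
# independent of the package's Romberg machinery.
simpson_oracle <- function(f, lower, upper, panels = 10000L) {
  if (upper == lower) return(0)
  x <- seq(lower, upper, length.out = 2L * panels + 1L)
  h <- (upper - lower) / (2 * panels)
  fx <- f(x)
  w <- rep(c(2, 4), panels)
  w[1L] <- 1
  h / 3 * sum(c(w, 1) * fx)
}

# Constant-rate illness-death model built from plain functions (exercises the
# function-rate code path; min_age 0).
constant_rates <- function(i, m0, m1 = m0) {
  force(i); force(m0); force(m1)
  illness_death_rates(
    incidence = function(t, a) rep_len(i, length(a)),
    mortality_healthy = function(t, a) rep_len(m0, length(a)),
    mortality_diseased = function(t, a, d) rep_len(m1, length(a)),
    time_origin = 0)
}
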