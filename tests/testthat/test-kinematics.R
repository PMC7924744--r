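test_that("trace construction enforces the sampling contract", {
  t <- seq(0, 7e-4, by = 1e-4)
  expect_error(strike_trace(t, seq_along(t))[1], NA)
  expect_error(strike_trace(t[1:5], 1:5), "at least 8")
  tb <- t; tb[4] <- tb[4] + 1e-6
  expect_error(strike_trace(tb, seq_along(t)), "non-uniform")
  # degrees converted on ingest
  tr <- strike_trace(t, rep(90, 8), unit = "deg")
  expect_equal(tr$angle, rep(pi / 2, 8))
})

test_that("spline derivatives recover polynomial and logistic truths", {
  # constant-rate trace: velocity flat, acceleration negligible
  s <- simulate_strike("linear", amplitude = 1, timescale = 1e-3,
                       fps = 1e5, seed = 1)
  d <- smooth_and_differentiate(s$trace)
  i <- 6:(nrow(d) - 5)
  expect_lt(max(abs(d$omega[i] - s$truth$omega_max)) / s$truth$omega_max, 1e-3)
  expect_lt(max(abs(d$alpha[i])), 1e-3 * s$truth$omega_max / 1e-3)

  # quadratic: constant angular acceleration recovered within 1%
  sq <- simulate_strike("quadratic", amplitude = 1.2, timescale = 1e-3,
                        fps = 1e5, seed = 1)
  dq <- smooth_and_differentiate(sq$trace)
  iq <- 6:(nrow(dq) - 5)
  expect_lt(abs(max(abs(dq$alpha[iq])) - sq$truth$alpha_max) /
              sq$truth$alpha_max, 0.01)

  # noisy logistic: omega_max within 5% over seeded replicates
  errs <- vapply(1:20, function(sd) {
    sl <- simulate_strike("logistic", amplitude = 1.2, timescale = 1e-3,
                          fps = 1e5, noise_sd = 0.5 * pi / 180, seed = sd)
    dl <- smooth_and_differentiate(sl$trace)
    il <- 6:(nrow(dl) - 5)
    abs(max(abs(dl$omega[il])) - sl$truth$omega_max) / sl$truth$omega_max
  }, numeric(1))
  expect_lt(median(errs), 0.05)
  expect_lt(max(errs), 0.10)
})

test_that("analytic strike truths agree with dense numerical differentiation", {
  s <- simulate_strike("logistic", amplitude = 2, timescale = 1e-3, fps = 2e4)
  expect_equal(num_deriv_max(s$truth$theta, 0, 1e-3, order = 1),
               s$truth$omega_max, tolerance = 1e-5)
  expect_equal(num_deriv_max(s$truth$theta, 0, 1e-3, order = 2),
               s$truth$alpha_max, tolerance = 1e-4)
})

test_that("strike duration uses excursion threshold crossings", {
  t <- seq(0, 1e-3, length.out = 101)
  ramp <- t / 1e-3
  expect_equal(strike_duration(t, ramp, 0, 1), 1e-3, tolerance = 1e-12)
  expect_equal(strike_duration(t, ramp, 0.02, 0.98), 0.96e-3, tolerance = 1e-9)
  expect_error(strike_duration(t, rep(0, 101)), "zero angular excursion")
  # logistic: crossing-time difference matches analytic root finding
  A <- 1; t0 <- 5e-4; tau <- 5e-5
  th <- A / (1 + exp(-(t - t0) / tau))
  lo <- th[1] + 0.02 * (th[101] - th[1])
  hi <- th[1] + 0.98 * (th[101] - th[1])
  inv <- function(y) t0 - tau * log(A / y - 1)
  # agreement within one frame interval (linear interpolation on the grid)
  expect_lt(abs(strike_duration(t, th, 0.02, 0.98) - (inv(hi) - inv(lo))),
            diff(t)[1])
})

test_that("thin-rod kinetic energy follows the closed form and scaling laws", {
  expect_equal(rotational_ke(6e-9, 1e-3, 1e3), 1e-9, tolerance = 1e-12)
  expect_equal(rotational_ke(6e-9, 1e-3, 0), 0)
  expect_equal(rotational_ke(6e-9, 1e-3, 2e3) / rotational_ke(6e-9, 1e-3, 1e3), 4)
  expect_equal(rotational_ke(6e-9, 2e-3, 1e3) / rotational_ke(6e-9, 1e-3, 1e3), 4)
  expect_error(rotational_ke(-1, 1, 1), "positive")
})

test_that("mass-specific power arithmetic and mandible count", {
  expect_equal(mass_specific_power(1e-9, 1e-6, 1e-8, 1), 1e5)
  expect_equal(mass_specific_power(1e-9, 1e-6, 1e-8, 2), 2e5)
  expect_equal(mass_specific_power(1e-9, 1e-6, 1e-5, 1), 100)
  expect_error(mass_specific_power(1e-9, 0, 1e-8), "positive")
})

test_that("power-amplification classification is exact at the boundary", {
  expect_false(classify_power_amplified(729))
  expect_false(classify_power_amplified(730))
  expect_true(classify_power_amplified(731))
  expect_false(classify_power_amplified(800, threshold = 1e3))
  v <- classify_power_amplified(c(100, 5000, 730.5))
  expect_equal(v, c(FALSE, TRUE, TRUE))
})

test_that("density-based mass estimation averages reference densities", {
  expect_equal(estimate_mass_by_density(2, 1, 0.5), 1)
  expect_equal(estimate_mass_by_density(c(1000, 4000), c(1, 2), 1e-12),
               1.5e-9)
  # equal densities recover rho * V exactly
  expect_equal(estimate_mass_by_density(c(2, 4, 6), c(1, 2, 3), 7), 14)
  expect_error(estimate_mass_by_density(numeric(0), numeric(0), 1), "empty")
  expect_equal(estimate_muscle_mass(1e-8, 2e-12, 2e-12), 1e-8)
  expect_equal(estimate_muscle_mass(1e-8, 2e-12, 4e-12), 2e-8)
  expect_error(estimate_muscle_mass(0, 1, 1), "positive")
})

test_that("summaries are invariant to frame rate and monotone in inputs", {
  spec <- list(mandible_length = 1e-3, mandible_mass = 6e-9,
               adductor_mass = 1e-8)
  s1 <- simulate_strike("logistic", amplitude = 1.2, timescale = 1e-3,
                        fps = 5e4, seed = 1)
  s2 <- simulate_strike("logistic", amplitude = 1.2, timescale = 1e-3,
                        fps = 1e5, seed = 1)
  k1 <- strike_summary(s1$trace, spec)
  k2 <- strike_summary(s2$trace, spec)
  expect_lt(abs(k1$omega_max - k2$omega_max) / k2$omega_max, 0.01)
  expect_lt(abs(k1$alpha_max - k2$alpha_max) / k2$alpha_max, 0.01)
  # v_max and a_max tied to the tip radius by construction
  expect_equal(k1$v_max, k1$omega_max * spec$mandible_length)
  expect_equal(k1$a_max, k1$alpha_max * spec$mandible_length)
  # heavier muscle lowers mass-specific power; flag is monotone
  spec_heavy <- spec; spec_heavy$adductor_mass <- spec$adductor_mass * 100
  k3 <- strike_summary(s2$trace, spec_heavy)
  expect_lt(k3$power_w_per_kg, k2$power_w_per_kg)
  expect_equal(k3$power_w_per_kg * 100, k2$power_w_per_kg, tolerance = 1e-9)
})

test_that("trap-jaw vs gripping trace pair reproduces the qualitative contrast", {
  # L-TRAP: 50 us strike at high frame rate; GRP: 10 ms at video rates
  trap <- simulate_strike("logistic", amplitude = 1.2, timescale = 5e-5,
                          fps = 8e5, seed = 1)
  grip <- simulate_strike("logistic", amplitude = 1.2, timescale = 1e-2,
                          fps = 2500, seed = 1)
  spec <- list(mandible_length = 5e-4, mandible_mass = 6e-9,
               adductor_mass = 2e-8)
  kt <- strike_summary(trap$trace, spec)
  kg <- strike_summary(grip$trace, spec)
  expect_gte(log10(kt$alpha_max / kg$alpha_max), 4)
  expect_true(kt$amplified)
  expect_false(kg$amplified)
  expect_lt(kt$duration_s, kg$duration_s)
})
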