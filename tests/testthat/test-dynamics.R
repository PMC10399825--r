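test_that("joint torque combines flexor and extensor through their moment arms", {
  expect_equal(joint_torque(0, 0, 0.05, 0.04), 0)
  expect_equal(joint_torque(1000, 0, 0.0469, 0.04), 46.9)
  expect_equal(joint_torque(1000, 1250, 0.05, 0.04), 0)  # co-contraction cancels
  expect_error(joint_torque(-1, 0, 0.05, 0.04),
               class = "myoelbow_invalid_argument_error")
})

test_that("gravity torque follows sin(alpha + theta) and flips overhead", {
  expect_equal(gravity_torque(0, 0, 1.456, 0.56, 2, 0.126, 0.30), 0)
  expect_equal(gravity_torque(pi / 2, 0, 1.456, 0.56, 2, 0.126, 0.30),
               -9.334, tolerance = 1e-3)
  expect_equal(gravity_torque(pi / 2, pi, 1.456, 0.56, 2, 0.126, 0.30),
               9.334, tolerance = 1e-3)
})

test_that("passive fall under gravity extends the arm and dissipates energy", {
  fixed <- average_fixed
  cond <- condition(alpha = 0, m_add = 2)
  n <- round(4 * FS)
  sim <- forward_simulate(zero_excitation(n), FS, fixed, free_parameters(),
                          cond, theta0 = pi / 2, omega0 = 0)
  expect_true(all(diff(sim$theta) <= 1e-12))       # monotone toward extension
  expect_lt(sim$theta[n], deg2 <- 30 * pi / 180)   # well clear of the start

  # total mechanical energy (kinetic + gravitational + muscle elastic)
  J <- fixed$m_forearm * fixed$L_forearm_cog^2 +
    (fixed$m_hand + cond$m_add) * fixed$L_palm^2
  G <- fixed$m_forearm * fixed$L_forearm_cog +
    (fixed$m_hand + cond$m_add) * fixed$L_palm
  elastic <- function(L, L0, F_max) {
    s <- pmax((L - L0) / L0, 0)
    F_max * fixed$K_p * L0 * s^3 / 3
  }
  L_b <- muscle_length_bic(
    sqrt(fixed$A_bic^2 + fixed$B_bic^2 +
           2 * fixed$A_bic * fixed$B_bic * cos(sim$theta)), fixed$L_T_bic)
  L_t <- muscle_length_tric(sim$theta, fixed$L_M0_tric, fixed$Lma_tric)
  E <- 0.5 * J * sim$omega^2 - fixed$g * G * cos(sim$theta) +
    elastic(L_b, fixed$L_M0_bic, fixed$F_max_bic) +
    elastic(L_t, fixed$L_M0_tric, fixed$F_max_tric)
  expect_lt(max(diff(E)), 1e-6)
  expect_lt(E[n], E[1])
})

test_that("without excitation and gravity the joint is damped to rest", {
  fixed <- average_fixed
  fixed$g <- 0
  n <- round(2 * FS)
  # equilibrium: no torque sources at all from a slack configuration
  sim0 <- forward_simulate(zero_excitation(n), FS, fixed, free_parameters(),
                           condition(m_add = 0), theta0 = 1.05, omega0 = 0)
  expect_equal(sim0$theta, rep(1.05, n), tolerance = 1e-9)
  # pure damping: |omega| non-increasing while both muscles stay slack
  sim <- forward_simulate(zero_excitation(n), FS, fixed, free_parameters(),
                          condition(m_add = 0), theta0 = 1.02, omega0 = 0.3)
  expect_true(all(sim$torque_bic_passive == 0))
  expect_true(all(sim$torque_tric_passive == 0))
  expect_true(all(diff(abs(sim$omega)) <= 1e-12))
})

test_that("the torque decomposition sums exactly to the integrated net torque", {
  trial <- cached_trial()
  sim <- simulate_trial(trial, average_fixed, trial$meta$true_free)
  total <- sim$torque_bic_active + sim$torque_tric_active +
    sim$torque_bic_passive + sim$torque_tric_passive +
    sim$torque_gravity + sim$torque_damping + sim$torque_stop
  # identical up to summation order
  expect_equal(total, sim$torque_net, tolerance = 1e-13)
})

test_that("replaying identical inputs reproduces the trajectory bit-identically", {
  trial <- cached_trial()
  s1 <- simulate_trial(trial, average_fixed, trial$meta$true_free)
  s2 <- simulate_trial(trial, average_fixed, trial$meta$true_free)
  expect_identical(s1$theta, s2$theta)
  # the synthetic measured angle is this forward solution; replay starts
  # from a cold filter state, whose transient has decayed by the end of the
  # static phase
  after <- trial$time > 5
  expect_lt(max(abs(s1$theta[after] - trial$theta_meas[after])), 1e-3)
})

test_that("halving the integration step changes the solution below 0.1 deg RMS", {
  trial <- cached_trial()
  fixed <- average_fixed
  filt <- bandpass_design(FS, fixed$f_low, fixed$f_high, fixed$filter_order)
  base <- vapply(1:4, function(j) {
    as.numeric(preprocess_emg(trial$emg[, j], 1, filt, clamp = FALSE))
  }, numeric(nrow(trial$emg)))
  s1 <- forward_simulate(base, FS, fixed, trial$meta$true_free, trial$cond)
  s2 <- forward_simulate(base, FS, fixed, trial$meta$true_free, trial$cond,
                         n_sub = 2L)
  rms_deg <- sqrt(mean((s1$theta - s2$theta)^2)) * 180 / pi
  expect_lt(rms_deg, 0.1)
})

test_that("a diverging simulation reports the failing step", {
  fixed <- average_fixed
  fixed$d_damp <- -1e6  # strong negative damping pumps energy in
  expect_error(
    forward_simulate(zero_excitation(round(2 * FS)), FS, fixed,
                     free_parameters(), condition(), theta0 = 1, omega0 = 1),
    regexp = "diverged")
})
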