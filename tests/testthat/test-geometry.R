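A <- 0.3978
B <- 0.0472

test_that("biceps auxiliary angle matches its boundary and worked values", {
  expect_equal(phi_bic(0, A, B), 0)
  expect_equal(rad2deg <- phi_bic(pi / 2, A, B) * 180 / pi, 83.23, tolerance = 1e-2)
  expect_equal(phi_bic(pi, A, B), pi)  # degenerate, excluded by the sim range
})

test_that("biceps moment arm is B sin(phi), bounded by B", {
  expect_equal(moment_arm_bic(0, B), 0)
  expect_equal(moment_arm_bic(pi / 2, B), B)
  expect_lt(abs(moment_arm_bic(phi_bic(pi / 2, A, B), B) - 0.04688), 1e-5)
  th <- seq(0, 150, by = 1) * pi / 180
  lma <- moment_arm_bic(phi_bic(th, A, B), B)
  expect_true(all(lma >= 0 & lma <= B + 1e-15))
})

test_that("projected MTC length equals the law-of-cosines form to 1e-12", {
  th <- seq(0, 150, by = 0.5) * pi / 180
  phi <- phi_bic(th, A, B)
  lhs <- mtc_length_bic(th, phi, A, B)
  rhs <- sqrt(A^2 + B^2 + 2 * A * B * cos(th))
  expect_lt(max(abs(lhs - rhs)), 1e-12)
  expect_equal(mtc_length_bic(0, 0, A, B), A + B)
  expect_equal(mtc_length_bic(pi / 2, phi_bic(pi / 2, A, B), A, B),
               sqrt(A^2 + B^2), tolerance = 1e-12)
})

test_that("biceps muscle length is MTC minus tendon", {
  expect_equal(muscle_length_bic(0.4006, 0.2540), 0.1466, tolerance = 1e-12)
  expect_error(muscle_length_bic(0.2, 0.254), class = "myoelbow_geometry_error")
  # resting consistency: where L_MTC = L_MTC0, the muscle sits at L_M0
  p <- average_fixed
  expect_equal(muscle_length_bic(p$L_MTC0_bic, p$L_T_bic), p$L_M0_bic)
})

test_that("triceps pulley length spans 0.54 to 1.41 L_M0 over 120 degrees", {
  p <- average_fixed
  expect_equal(muscle_length_tric(0, p$L_M0_tric, p$Lma_tric),
               0.54 * p$L_M0_tric, tolerance = 1e-15)
  expect_equal(muscle_length_tric(2 * pi / 3, p$L_M0_tric, p$Lma_tric),
               1.41 * p$L_M0_tric, tolerance = 1e-12)
  th <- seq(0, 150, by = 1) * pi / 180
  L <- muscle_length_tric(th, p$L_M0_tric, p$Lma_tric)
  expect_true(all(diff(L) > 0))  # the extensor stretches with flexion
  expect_equal(muscle_length_tric(1, p$L_M0_tric, p$Lma_tric, L_offset = 0.01) -
                 muscle_length_tric(1, p$L_M0_tric, p$Lma_tric), 0.01)
  expect_error(muscle_length_tric(0, p$L_M0_tric, p$Lma_tric, L_offset = -0.06),
               class = "myoelbow_geometry_error")
})

test_that("muscle velocities: pulley is exact, biceps matches the chain rule", {
  p <- average_fixed
  n <- 2000L
  tm <- (seq_len(n) - 1) / FS
  # constant angle: both velocities vanish
  v0 <- muscle_velocities(rep(1, n), FS, p)
  expect_true(all(abs(v0$v_M_bic) < 1e-12) && all(abs(v0$v_M_tric) < 1e-12))
  # smooth sine trajectory
  th <- pi / 2 + 0.6 * sin(2 * pi * 0.5 * tm)
  v <- muscle_velocities(th, FS, p)
  omega <- 0.6 * 2 * pi * 0.5 * cos(2 * pi * 0.5 * tm)
  expect_equal(v$v_M_tric, p$Lma_tric * v$omega, tolerance = 1e-12)
  # analytic dL_MTC/dtheta * omega
  L_MTC <- sqrt(p$A_bic^2 + p$B_bic^2 + 2 * p$A_bic * p$B_bic * cos(th))
  v_ref <- -(p$A_bic * p$B_bic * sin(th)) / L_MTC * omega
  core <- 10:(n - 10)
  expect_lt(max(abs(v$v_M_bic[core] - v_ref[core])) / max(abs(v_ref)), 1e-3)
})
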