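test_that("segmentation finds the static hold and three movement periods", {
  trial <- cached_trial()
  seg <- segment_trial(trial$theta_meas, trial$fs, trial$cond$target_freq)
  static_s <- diff(seg$static_span) / trial$fs
  expect_gt(static_s, 4.5)
  expect_lt(static_s, 5.6)
  expect_length(seg$period_spans, 3L)
  for (sp in seg$period_spans) {
    expect_equal(diff(sp) / trial$fs, 1 / trial$cond$target_freq,
                 tolerance = 0.1)
  }
  expect_error(segment_trial(rep(pi / 2, 5000), FS, 0.25),
               class = "myoelbow_segmentation_error")
})

test_that("static gains are estimated for the gravity-loaded muscle only", {
  trial <- cached_trial()
  k1 <- estimate_static_gains(trial, average_fixed)
  est <- attr(k1, "estimated")
  expect_identical(est, c(TRUE, TRUE, FALSE, FALSE))  # lower posture: biceps
  expect_true(all(k1[1:2] > 0))
  expect_identical(unname(k1[3:4]), c(1, 1))

  # doubling the added mass scales the estimate with the static torque
  cond2 <- condition(alpha = trial$cond$alpha, m_add = 4,
                     target_freq = trial$cond$target_freq)
  k2 <- estimate_static_gains(trial, average_fixed, cond2)
  f <- average_fixed
  T1 <- f$m_forearm * f$L_forearm_cog + (f$m_hand + 2) * f$L_palm
  T2 <- f$m_forearm * f$L_forearm_cog + (f$m_hand + 4) * f$L_palm
  expect_equal(unname(k2[1] / k1[1]), T2 / T1, tolerance = 1e-12)

  # upper posture: the triceps carries the load
  up <- make_trial(synthetic_trial_spec(
    cond = condition(alpha = pi, m_add = 2, target_freq = 0.25), seed = 5L))
  ku <- estimate_static_gains(up, average_fixed)
  expect_identical(attr(ku, "estimated"), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(ku[3:4] > 0))
})

test_that("bounds scale with the gain estimate; the offset bound is fixed", {
  b1 <- parameter_bounds(c(1, 1, 1, 1))
  expect_equal(unname(b1$lower), c(0.1, 0.1, 0.1, 0.1, -0.05))
  expect_equal(unname(b1$upper), c(5, 5, 5, 5, 0.05))
  b2 <- parameter_bounds(c(2, 2, 2, 2))
  expect_equal(unname(b2$lower[1:4]), rep(0.2, 4))
  expect_equal(unname(b2$upper[1:4]), rep(10, 4))
  expect_equal(unname(b2$lower[5]), -0.05)
})

test_that("the random-walk search is a deterministic box argmin", {
  centre <- c(1.2, 0.8, 2, 0.5, 0.01)
  obj <- function(p) sum((p - centre)^2)
  bounds <- parameter_bounds(c(1, 1, 1, 1))
  r1 <- random_walk_search(obj, bounds, n_sets = 300, seed = 9)
  r2 <- random_walk_search(obj, bounds, n_sets = 300, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$par >= bounds$lower & r1$par <= bounds$upper))
  # no corner of the box beats the returned point
  corners <- as.matrix(expand.grid(lapply(1:5, function(i) {
    c(bounds$lower[i], bounds$upper[i])
  })))
  expect_true(all(apply(corners, 1, obj) >= r1$sse))
})

test_that("local refinement never worsens the objective and fixes the optimum", {
  centre <- c(1, 1, 1, 1, 0)
  residual <- function(p) p - centre
  bounds <- parameter_bounds(c(1, 1, 1, 1))
  at_opt <- local_refine(centre, bounds, residual)
  expect_equal(at_opt$par, centre, tolerance = 1e-8)
  start <- c(2, 0.5, 3, 0.2, -0.03)
  ref <- local_refine(start, bounds, residual)
  expect_lte(ref$sse, sum(residual(start)^2))
  expect_equal(ref$par, centre, tolerance = 1e-6)
  # gains may be faded out to zero, below the random-walk lower bound
  res2 <- function(p) p - c(0, 1, 1, 1, 0)
  ref2 <- local_refine(c(0.5, 1, 1, 1, 0), bounds, res2)
  expect_lt(ref2$par[1], bounds$lower[1])
  expect_error(local_refine(c(NA, 1, 1, 1, 0), bounds, function(p) rep(NA_real_, 5)),
               class = "myoelbow_search_failure_error")
})

test_that("two-stage calibration recovers a synthetic trial", {
  trial <- cached_trial()
  cal <- calibrate_trial(trial, average_fixed, n_sets = 250L, seed = 3L)
  expect_lte(cal$sse, cal$sse_random_walk)
  truth <- as.numeric(unlist(trial$meta$true_free))
  got <- as.numeric(unlist(cal$free))
  expect_lt(max(abs(got[1:4] / truth[1:4] - 1)), 0.2)
  expect_lt(abs(got[5] - truth[5]), 0.005)
  expect_lt(cal$metrics$nmae, 0.05)
  expect_gt(cal$metrics$qs, 0.8)
})
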