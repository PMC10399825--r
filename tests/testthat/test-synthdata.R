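test_that("static tonic activation matches the posture's gravity load", {
  spec_lo <- synthetic_trial_spec(seed = 1L)
  prof_lo <- synth_activation_profiles(spec_lo, cocontraction = 0)
  static <- prof_lo$time < spec_lo$duration_static
  expect_gt(mean(prof_lo$a_bic[static]), 0.05)   # biceps holds the weight
  expect_lt(mean(prof_lo$a_tric[static]), 1e-6)

  spec_up <- synthetic_trial_spec(
    cond = condition(alpha = pi, m_add = 2, target_freq = 0.25), seed = 1L)
  prof_up <- synth_activation_profiles(spec_up, cocontraction = 0)
  expect_gt(mean(prof_up$a_tric[static]), 0.05)  # triceps holds overhead
  expect_lt(mean(prof_up$a_bic[static]), 1e-6)

  # no load, no gravity: tonic levels vanish
  fixed0 <- derive_fixed_parameters(spec_lo$anthro)
  fixed0$g <- 0
  spec0 <- synthetic_trial_spec(cond = condition(alpha = 0, m_add = 0,
                                                 target_freq = 0.25), seed = 1L)
  prof0 <- synth_activation_profiles(spec0, fixed0, cocontraction = 0)
  expect_lt(max(prof0$a_bic[static], prof0$a_tric[static]), 1e-6)
})

test_that("surrogate sEMG encodes the activation envelope recoverably", {
  n <- round(8 * FS)
  tm <- (seq_len(n) - 1) / FS
  a <- 0.3 + 0.2 * sin(2 * pi * 0.25 * tm)
  k_true <- 1.5
  raw <- synth_raw_emg(a, k_true, FS, noise_snr = 30, seed = 21L)
  e <- preprocess_emg(raw, k_true, fs = FS)
  u <- integrate_activation(e, FS)
  a_rec <- a_model(u)
  settle <- tm > 1
  expect_lt(sqrt(mean((a_rec[settle] - a[settle])^2)), 0.05)

  # construction properties
  expect_identical(synth_raw_emg(rep(0, 100), 1, FS, noise_snr = Inf, seed = 1L),
                   rep(0, 100))
  r1 <- synth_raw_emg(a, 2, FS, noise_snr = Inf, seed = 3L)
  r2 <- synth_raw_emg(a, 1, FS, noise_snr = Inf, seed = 3L)
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
})

test_that("generated trials are reproducible and byte-identical on disk", {
  spec <- synthetic_trial_spec(seed = 8L, duration_move = 14)
  t1 <- make_trial(spec)
  t2 <- make_trial(spec)
  expect_identical(t1$theta_meas, t2$theta_meas)
  expect_identical(t1$emg, t2$emg)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_trial(t1, f1)
  write_trial(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # the generator must not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(make_trial(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("the movement covers 90 +/- 45 degrees within 10 percent", {
  trial <- cached_trial()
  move <- trial$time > 5 + 1 / trial$cond$target_freq
  th <- trial$theta_meas[move] * 180 / pi
  width <- max(th) - min(th)
  centre <- (max(th) + min(th)) / 2
  expect_equal(width, 90, tolerance = 0.1)
  expect_equal(centre, 90, tolerance = 0.1)
})

test_that("the generator and the segmenter agree on the trial structure", {
  trial <- cached_trial()
  seg <- segment_trial(trial$theta_meas, trial$fs, trial$cond$target_freq)
  expect_equal(diff(seg$static_span) / trial$fs, 5, tolerance = 0.12)
  expect_gte(length(seg$period_spans), 3L)
})
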