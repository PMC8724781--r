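test_that("EMG baseline statistics come from a void-free filling window", {
  # constant rectified signal: mean c, sd 0
  b <- estimate_emg_baseline(rep(0.3, 1000), 100,
                             matrix(numeric(0), 0, 2), small_extract_params())
  expect_equal(b$mean, 0.3)
  expect_equal(b$sd, 0)
  # the guard can exclude everything
  expect_error(
    estimate_emg_baseline(rep(0.3, 1000), 100, matrix(c(0, 10), 1, 2),
                          small_extract_params(guard_s = 100)),
    "guard excludes")
  # on a simulated trace the baseline tracks the tonic envelope level
  cfg <- small_sim_config(n_cycles = 3)
  sim <- simulate_recording(cfg, rng_seed = 5)
  sf <- extract_session_features(sim$recording, small_extract_params())
  tonic_level <- cfg$tonic_amplitude * 2 / pi  # rectified carrier mean
  # additive noise inflates the rectified mean slightly above the envelope
  expect_lt(abs(sf$baseline$mean - tonic_level), 0.1 * tonic_level +
              cfg$baseline_noise_sd)
})

test_that("burst counting matches ground truth and is monotone in amplitude", {
  cfg <- small_sim_config(n_cycles = 3, noise = FALSE, cvw = zero_cv(),
                          feature_means = c(burst_count = 54,
                                            burst_duration = 6))
  sim <- simulate_recording(cfg, rng_seed = 6)
  cond <- condition_recording(sim$recording)
  sf <- extract_session_features(sim$recording, small_extract_params())
  expect_equal(sf$events$burst_count, c(54, 54, 54))
  # doubling the EMG with a fixed baseline cannot decrease the count
  b <- sf$baseline
  w <- c(sim$truth$onset_time[1] - 1, sim$truth$void_end_time[1])
  n1 <- count_burst_events(cond$emg, cond$rate, w, b, small_extract_params())
  n2 <- count_burst_events(cond$emg * 2, cond$rate, w, b,
                           small_extract_params())
  expect_gte(n2, n1)
  # no supra-threshold samples: zero, not an error
  expect_equal(count_burst_events(rep(0, 500), 100, c(0, 4), b,
                                  small_extract_params()), 0)
})

test_that("burst criteria are invariant to a common additive shift", {
  cfg <- small_sim_config(n_cycles = 3, noise = FALSE, cvw = zero_cv())
  sim <- simulate_recording(cfg, rng_seed = 10)
  cond <- condition_recording(sim$recording)
  sf <- extract_session_features(sim$recording, small_extract_params())
  b <- sf$baseline
  w <- c(sim$truth$onset_time[1] - 1, sim$truth$void_end_time[1])
  shift <- 0.25
  b2 <- b
  b2$mean <- b$mean + shift
  expect_equal(
    count_burst_events(cond$emg + shift, cond$rate, w, b2,
                       small_extract_params()),
    count_burst_events(cond$emg, cond$rate, w, b, small_extract_params()))
  q1 <- detect_quiet_periods(cond$emg, cond$rate, w, b, small_extract_params())
  q2 <- detect_quiet_periods(cond$emg + shift, cond$rate, w, b2,
                             small_extract_params())
  expect_equal(q1, q2)
})

test_that("quiet periods partition the bursting episode correctly", {
  cfg <- small_sim_config(n_cycles = 3, noise = FALSE, cvw = zero_cv(),
                          feature_means = c(burst_count = 20,
                                            burst_duration = 4))
  sim <- simulate_recording(cfg, rng_seed = 7)
  cond <- condition_recording(sim$recording)
  sf <- extract_session_features(sim$recording, small_extract_params())
  b <- sf$baseline
  crit <- b$mean + small_extract_params()$quiet_k * b$sd
  for (i in 1:2) {
    w <- c(sim$truth$onset_time[i] - 1, sim$truth$void_end_time[i])
    qp <- detect_quiet_periods(cond$emg, cond$rate, w, b,
                               small_extract_params())
    # B bursts are separated (and flanked) by B + 1 quiet gaps
    expect_lte(abs(nrow(qp) - (sim$truth$burst_count[i] + 1)), 1)
    expect_true(all(qp$end > qp$start))
    expect_true(all(qp$start >= w[1] & qp$end <= w[2]))
    # non-overlapping and sorted
    if (nrow(qp) > 1) expect_true(all(qp$start[-1] > qp$end[-nrow(qp)]))
    # no sample inside a quiet period exceeds the quiet criterion
    for (j in seq_len(nrow(qp))) {
      idx <- (round(qp$start[j] * cond$rate) + 1):(round(qp$end[j] * cond$rate) + 1)
      expect_true(all(cond$emg[idx] < crit))
    }
  }
  # constant supra-threshold signal: no quiet periods
  expect_equal(nrow(detect_quiet_periods(rep(1, 500), 100, c(0, 4), b,
                                         small_extract_params())), 0)
})

test_that("burst duration is the span from first to last quiet period", {
  qp <- data.frame(start = c(10.0, 17.9), end = c(10.05, 17.95))
  expect_equal(burst_duration(qp), 7.95)
  expect_equal(burst_duration(data.frame(start = 3, end = 4.5)), 1.5)
  expect_equal(burst_duration(data.frame(start = numeric(0),
                                         end = numeric(0))), 0)
  # noise-free recovery within one burst period of truth
  cfg <- small_sim_config(n_cycles = 3, noise = FALSE, cvw = zero_cv())
  sim <- simulate_recording(cfg, rng_seed = 8)
  sf <- extract_session_features(sim$recording, small_extract_params())
  period <- sim$truth$burst_duration / sim$truth$burst_count
  expect_true(all(abs(sf$events$burst_duration - sim$truth$burst_duration)
                  <= period + 0.02))
})
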