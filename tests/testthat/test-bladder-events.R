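test_that("noise-free cycles are detected with peak times matching truth", {
  cfg <- small_sim_config(n_cycles = 5, noise = FALSE, cvw = zero_cv())
  sim <- simulate_recording(cfg, rng_seed = 1)
  cond <- condition_recording(sim$recording)
  voids <- detect_voids(cond$pressure, cond$rate, small_extract_params())
  expect_equal(nrow(voids), 5)
  expect_equal(voids$peak_time, sim$truth$peak_time, tolerance = 0.02)
  expect_equal(voids$peak_pressure_raw,
               sim$truth$min_pressure + sim$truth$peak_pressure,
               tolerance = 0.01)
})

test_that("flat and sub-prominence traces yield an empty event list", {
  p <- small_extract_params()
  expect_equal(nrow(detect_voids(rep(1, 5000), 100, p)), 0)
  expect_equal(nrow(detect_voids(rnorm(5000, 0, 0.5), 100, p)), 0)
})

test_that("noise-free threshold pressure is recovered at the configured value", {
  cfg <- small_sim_config(n_cycles = 3, noise = FALSE, cvw = zero_cv())
  sim <- simulate_recording(cfg, rng_seed = 2)
  cond <- condition_recording(sim$recording)
  voids <- detect_voids(cond$pressure, cond$rate, small_extract_params())
  for (i in 1:3) {
    prev <- if (i == 1) 0 else voids$post_void_min_time[i - 1]
    th <- find_threshold_pressure(cond$pressure, cond$rate,
                                  voids$peak_time[i], prev,
                                  small_extract_params())
    expect_true(th$ok)
    # slope smearing can pull the crossing slightly into the filling ramp;
    # the pressure error is bounded by fill slope x kernel span
    expect_equal(th$threshold_pressure, 4.43, tolerance = 0.1)
    expect_equal(th$time, sim$truth$onset_time[i], tolerance = 1.5)
  }
})

test_that("a pure linear ramp has no slope change and is flagged", {
  ramp <- seq(0, 20, length.out = 12000)  # 120 s at 100 Hz
  th <- find_threshold_pressure(ramp, 100, peak_time = 119, prev_bound = 0,
                                small_extract_params())
  expect_false(th$ok)
  expect_true(is.na(th$threshold_pressure))
})

test_that("event features follow their defining arithmetic", {
  voids <- data.frame(peak_time = c(100, 427.3),
                      peak_pressure_raw = c(22.7, 23.0),
                      post_void_min_time = c(120, 447),
                      post_void_min_pressure = c(1.3, 1.2),
                      cycle_start = c(0, 120), cycle_end = c(120, 447))
  # synthetic conditioned trace: linear fills with clear contractions
  # not needed for the arithmetic checks; stub threshold detection by
  # building a trace whose onsets are recoverable is overkill here, so
  # verify measure_events on the peak-to-peak fiducial instead
  p <- small_extract_params(ici_fiducial = "peak")
  trace <- rep(1.3, 45000)
  ev <- measure_events(trace, 100, voids, infusion_rate = 0.088, p)
  expect_equal(ev$peak_pressure[1], 22.7 - 1.3)
  expect_equal(ev$min_pressure, c(1.3, 1.2))
  expect_equal(ev$ici[1], 327.3)
  expect_equal(ev$volume_threshold[1], 327.3 * 0.088 / 60)  # 0.48 ml
  expect_equal(ev$volume_threshold[1], 0.48, tolerance = 1e-3)
  expect_true(is.na(ev$ici[2]))
  expect_true(is.na(ev$volume_threshold[2]))
})

test_that("zero-noise extraction recovers every feature at effective resolution", {
  cfg <- small_sim_config(n_cycles = 3, noise = FALSE, cvw = zero_cv())
  sim <- simulate_recording(cfg, rng_seed = 3)
  # measurement smoothing exists to tame noise; off for the exactness check
  sf <- extract_session_features(sim$recording,
                                 small_extract_params(measure_smooth = 0))
  ev <- sf$events
  tr <- sim$truth
  expect_equal(ev$peak_pressure, tr$peak_pressure, tolerance = 1e-3)
  expect_equal(ev$min_pressure, tr$min_pressure, tolerance = 1e-3)
  expect_equal(ev$threshold_pressure, tr$threshold_pressure, tolerance = 0.1)
  expect_equal(ev$ici[1:2], tr$ici[1:2], tolerance = 0.1)
  expect_equal(ev$burst_count, tr$burst_count)
  expect_equal(ev$burst_duration, tr$burst_duration, tolerance = 0.05)
  # conservation: volume / ici identical to the metadata infusion rate
  ok <- !is.na(ev$ici)
  expect_equal(ev$volume_threshold[ok] / ev$ici[ok],
               rep(0.088 / 60, sum(ok)), tolerance = 1e-14)
  # ordering invariant on accepted events
  expect_true(all(ev$min_pressure <= ev$threshold_pressure))
  expect_true(all(ev$threshold_pressure <= ev$min_pressure + ev$peak_pressure))
})

test_that("features are invariant to a constant pressure shift", {
  cfg <- small_sim_config(n_cycles = 3, noise = FALSE, cvw = zero_cv())
  sim <- simulate_recording(cfg, rng_seed = 4)
  a <- extract_session_features(sim$recording, small_extract_params())
  shifted <- sim$recording
  shifted$pressure <- shifted$pressure + 12.5
  b <- extract_session_features(shifted, small_extract_params())
  expect_equal(a$table$value, b$table$value, tolerance = 1e-10)
})

test_that("stable-window selection minimizes ICI variability with documented ties and overrides", {
  mk <- function(ici) data.frame(
    event_index = seq_along(ici), onset_time = cumsum(c(100, head(ici, -1))),
    ici = ici, threshold_pressure = 5, ok = TRUE)
  # exactly n valid events: that window
  expect_equal(select_stable_events(mk(c(60, 61, 59, 60, 62)), n = 5), 1:5)
  # middle window with identical ICIs wins
  f <- mk(c(80, 95, 70, 70, 70, 70, 70, 90, 60, 85))
  expect_equal(select_stable_events(f, n = 5), 3:7)
  # user start time overrides
  expect_equal(select_stable_events(f, n = 3,
                                    start_time = f$onset_time[6]), 6:8)
  # insufficiency names the count found
  expect_error(select_stable_events(mk(c(60, 61)), n = 5),
               "found 2 valid")
  # events failing threshold detection break contiguity
  g <- mk(rep(60, 7))
  g$ok[4] <- FALSE
  expect_error(select_stable_events(g, n = 5), "insufficient")
  # both remaining runs tie at CV = 0; the earliest window wins
  expect_equal(select_stable_events(g, n = 3), 1:3)
})
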