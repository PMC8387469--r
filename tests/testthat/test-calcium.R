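test_that("dF/F matches the hand-computed example and its invariants", {
  expect_equal(delta_f_over_f(c(1, 1, 1, 3)), c(-1 / 3, -1 / 3, -1 / 3, 1))
  expect_true(all(delta_f_over_f(rep(7, 10)) == 0))
  set.seed(5)
  f <- runif(500, 50, 150)
  expect_lt(abs(mean(delta_f_over_f(f))), 1e-12)
  # scale invariance
  expect_equal(delta_f_over_f(3.7 * f), delta_f_over_f(f), tolerance = 1e-9)
  expect_error(delta_f_over_f(c(-2, 0, 2)), "positive")
  # matrix input normalizes per column
  m <- cbind(f, 2 * f)
  dm <- delta_f_over_f(m)
  expect_equal(dm[, 1], dm[, 2], tolerance = 1e-9)
})

test_that("detector finds planted suprathreshold transients", {
  fs <- 15
  tt <- (0:(900 * fs - 1)) / fs
  set.seed(2)
  noise <- rnorm(length(tt))
  mk <- function(onsets, amp = 5) {
    tr <- noise
    for (o in onsets) tr <- tr + amp * calcium_kernel(tt - o)
    tr <- tr + 100
    delta_f_over_f(tr)
  }
  ev1 <- detect_events(mk(450), fs)
  expect_length(ev1, 1)
  expect_lt(abs(ev1 - 450), 0.5)
  ev2 <- detect_events(mk(c(300, 310)), fs)
  expect_length(ev2, 2)
})

test_that("raising k_sigma never increases the event count", {
  set.seed(9)
  sim <- simulate_calcium_traces(
    calcium_sim_params(event_rate = 6, duration = 600,
                       transient_amplitude = 4, seed = 9))
  dff <- delta_f_over_f(sim$traces[, 1])
  counts <- vapply(c(1, 2, 3, 4, 6, 10), function(k) {
    length(detect_events(dff, 15, event_detect_config(k_sigma = k)))
  }, 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("false positives on pure noise stay below half an event per minute", {
  fp <- vapply(1:5, function(s) {
    set.seed(s)
    dff <- delta_f_over_f(100 + rnorm(900 * 15, sd = 3))
    length(detect_events(dff, 15)) / 15
  }, 1)
  expect_true(all(fp <= 0.5))
})

test_that("short traces are rejected by the smoother", {
  expect_error(detect_events(rnorm(5), 15, event_detect_config(smoothing_sigma = 3)),
               "smoothing support")
})

test_that("events per minute obeys its defining identity", {
  r <- events_per_minute(seq(0, 890, length.out = 30), 900)
  expect_equal(r$events_per_minute, 2.0)
  expect_equal(events_per_minute(numeric(0), 300)$events_per_minute, 0)
  expect_error(events_per_minute(1, -5), "duration")
  expect_equal(r$events_per_minute,
               60 * length(r$event_times) / r$recording_duration)
})

test_that("rate comparison separates conditions with distinct planted rates", {
  set.seed(3)
  a <- rnorm(50, 2, 0.5); b <- rnorm(50, 4, 0.5)
  tt <- compare_event_rates(a, b)
  expect_lt(tt$p.value, 0.05)
  expect_equal(unname(tt$statistic), welch_t_oracle(a, b), tolerance = 1e-10)
})

test_that("ROI extraction averages the disk and respects bounds", {
  movie <- array(10, c(20, 20, 3))
  tr <- extract_roi_traces(movie, roi_spec(c(10, 10), 4))
  expect_true(all(tr == 10))
  expect_error(extract_roi_traces(movie, roi_spec(c(2, 2), 4)), "leaves the frame")
  # planted source: trace proportional to source brightness
  br <- c(5, 10, 20)
  mp <- movie_sim_params(frame_shape = c(40, 40), n_frames = 3,
                         roi_centers = matrix(c(20, 20), 1), roi_radius = 6,
                         baseline_level = 0,
                         source_traces = matrix(br, 3, 1))
  mv <- simulate_movie(mp)
  tr2 <- extract_roi_traces(mv$movie, roi_spec(c(20, 20), 6))
  expect_equal(as.numeric(tr2 / br), rep(tr2[1] / br[1], 3), tolerance = 1e-12)
  # two disjoint ROIs track their own sources
  set.seed(6)
  s1 <- runif(20, 0, 40); s2 <- runif(20, 0, 40)
  mp2 <- movie_sim_params(frame_shape = c(60, 60), n_frames = 20,
                          roi_centers = rbind(c(18, 18), c(42, 42)),
                          roi_radius = 6, baseline_level = 5,
                          source_traces = cbind(s1, s2))
  mv2 <- simulate_movie(mp2)
  tr3 <- extract_roi_traces(mv2$movie, list(roi_spec(c(18, 18), 6, "a"),
                                            roi_spec(c(42, 42), 6, "b")))
  expect_gt(cor(tr3[, "a"], s1), 0.999)
  expect_gt(cor(tr3[, "b"], s2), 0.999)
  expect_lt(abs(cor(tr3[, "a"], s2)), 0.3)
})

test_that("motion correction recovers planted integer shifts exactly", {
  set.seed(4)
  # drift excursions around a dominant resting pose (per-axis median 0)
  shifts <- cbind(c(0, 0, 0, 3, -4, 5, 0, -2, 0, 1, -5, 0),
                  c(0, 0, -3, 0, 2, -5, 0, 4, 0, -1, 5, 0))
  mp <- movie_sim_params(frame_shape = c(48, 48), n_frames = 12,
                         roi_centers = rbind(c(20, 24), c(30, 18)),
                         roi_radius = 5, drift_shifts = shifts,
                         baseline_level = 20, source_amplitude = 40)
  mv <- simulate_movie(mp)
  pp <- preprocess_movie(mv$movie, homomorphic = FALSE, background = FALSE,
                         max_shift = 6)
  expect_equal(pp$shifts, shifts)
})

test_that("preprocessing is a near-identity on a flat static movie", {
  mp <- movie_sim_params(frame_shape = c(48, 48), n_frames = 4,
                         roi_centers = matrix(c(24, 24), 1), roi_radius = 6,
                         baseline_level = 30, source_amplitude = 20)
  mv <- simulate_movie(mp)
  pp <- preprocess_movie(mv$movie, background = FALSE, max_shift = 3)
  expect_equal(pp$shifts, matrix(0L, 4, 2), ignore_attr = TRUE)
  # compact sources survive the illumination filter up to modest attenuation
  rel <- abs(pp$movie - mv$movie) / max(mv$movie)
  expect_lt(stats::quantile(rel, 0.99), 0.2)
})

test_that("homomorphic filtering removes a smooth gain field", {
  set.seed(12)
  fs <- c(48, 48)
  gain <- outer(seq(0.6, 1.4, length.out = fs[1]),
                seq(0.7, 1.3, length.out = fs[2]))
  base <- movie_sim_params(frame_shape = fs, n_frames = 6,
                           roi_centers = rbind(c(16, 20), c(34, 30)),
                           roi_radius = 5, baseline_level = 25,
                           source_traces = matrix(runif(12, 10, 60), 6, 2))
  clean <- simulate_movie(base)$movie
  shaded_params <- base
  shaded_params$illumination_field <- gain
  shaded <- simulate_movie(shaded_params)$movie
  corr <- preprocess_movie(shaded, motion = FALSE, background = FALSE,
                           lowpass_sigma = 12)$movie
  r_raw <- cor(as.vector(shaded), as.vector(clean))
  r_corr <- cor(as.vector(corr), as.vector(clean))
  expect_gt(r_corr, r_raw)
})

test_that("frames of differing shape are rejected", {
  expect_error(preprocess_movie(array(1, c(10, 10))), "frames")
  expect_error(preprocess_movie(array(1, c(10, 10, 1))), "2 frames")
})
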