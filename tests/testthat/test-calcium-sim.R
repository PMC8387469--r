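test_that("parameter validation rejects nonphysical configurations", {
  expect_error(calcium_sim_params(rise_tau = 1, decay_tau = 0.5), "decay_tau")
  expect_error(calcium_sim_params(sampling_rate = 0), "sampling_rate")
  expect_error(calcium_sim_params(noise_sd = -1), "noise_sd")
})

test_that("silent noiseless traces sit at baseline", {
  sim <- simulate_calcium_traces(
    calcium_sim_params(event_rate = 0, noise_sd = 0, duration = 60,
                       baseline_level = 80, seed = 1))
  expect_true(all(sim$traces == 80))
  expect_length(sim$event_times[[1]], 0)
})

test_that("planted event counts track rate x duration", {
  n <- vapply(1:20, function(s) {
    sim <- simulate_calcium_traces(
      calcium_sim_params(event_rate = 4, duration = 900, seed = s))
    length(sim$event_times[[1]])
  }, 1)
  expect_gt(mean(n), 60 * 0.85)
  expect_lt(mean(n), 60 * 1.15)
})

test_that("transient amplitude equals its nominal multiple of the noise SD", {
  # unit-peak kernel: max of the clean trace above baseline ~ amplitude
  tpk <- 0.2 * 1.0 / (1.0 - 0.2) * log(1.0 / 0.2)
  expect_equal(max(calcium_kernel(seq(0, 5, by = 1e-4))), 1, tolerance = 1e-6)
  expect_equal(calcium_kernel(tpk), 1)
  expect_equal(calcium_kernel(-1), 0)
  sim <- simulate_calcium_traces(
    calcium_sim_params(event_rate = 1, duration = 300, noise_sd = 1,
                       transient_amplitude = 5, seed = 4))
  stopifnot(length(sim$event_times[[1]]) > 0)
  expect_equal(max(sim$traces[, 1] - sim$params$baseline_level), 5,
               tolerance = 0.2 * 5)
})

test_that("trace generation is deterministic under a fixed seed", {
  p <- calcium_sim_params(event_rate = 3, duration = 120, n_rois = 3, seed = 8)
  expect_identical(simulate_calcium_traces(p), simulate_calcium_traces(p))
})

test_that("noiseless static movies repeat the same frame", {
  mp <- movie_sim_params(frame_shape = c(32, 32), n_frames = 4,
                         roi_centers = matrix(c(16, 16), 1), roi_radius = 5)
  mv <- simulate_movie(mp)
  for (t in 2:4) expect_equal(mv$movie[, , t], mv$movie[, , 1])
})

test_that("planted drift translates frames exactly when noiseless", {
  shifts <- rbind(c(0, 0), c(3, -2))
  mp <- movie_sim_params(frame_shape = c(40, 40), n_frames = 2,
                         roi_centers = matrix(c(20, 20), 1), roi_radius = 6,
                         drift_shifts = shifts, baseline_level = 10,
                         source_amplitude = 30)
  mv <- simulate_movie(mp)
  manual <- striatlearn:::shift_frame(mv$movie[, , 1], 3, -2, fill = 10)
  expect_equal(mv$movie[, , 2], manual)
})

test_that("a drifting disk may not leave the frame", {
  expect_error(
    movie_sim_params(frame_shape = c(32, 32), n_frames = 2,
                     roi_centers = matrix(c(5, 5), 1), roi_radius = 4,
                     drift_shifts = rbind(c(0, 0), c(-3, 0))),
    "leaves the frame")
})
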