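test_that("schedule config validates its fields", {
  expect_error(schedule_config("FR1", criterion_rewards = 0), "criterion")
  expect_error(schedule_config("RI60", ri_activation_prob = 0), "\\(0, 1\\]")
  expect_error(schedule_config("FR1", session_cap = -5), "session_cap")
})

test_that("FR1 rewards every eligible press and stops at criterion", {
  ses <- simulate_operant_session(
    schedule_config("FR1", criterion_rewards = 30),
    regular_press_times(3600, interval = 2), seed = 1)
  expect_identical(ses$n_rewards, 30L + 0L)
  # presses 2 s apart are all outside the 1-s timeout: 30th press = 60 s
  expect_equal(ses$session_end, 60)
  expect_equal(sum(ses$events$event_type == "press"), 30)
})

test_that("FR1 timeout suppresses rewards for presses inside the lockout", {
  # presses every 0.5 s with a 1-s timeout: only every other press earns
  ses <- simulate_operant_session(
    schedule_config("FR1", criterion_rewards = 10, timeout = 1),
    seq(0.5, 60, by = 0.5), seed = 1)
  rw <- ses$events$time_s[ses$events$event_type == "reward"]
  expect_length(rw, 10)
  expect_true(all(diff(rw) >= 1))
})

test_that("FR2 rewards every second eligible press", {
  ses <- simulate_operant_session(
    schedule_config("FR2", criterion_rewards = 10),
    regular_press_times(3600, interval = 2), seed = 1)
  expect_identical(ses$n_rewards, 10L + 0L)
  # 10 rewards need 20 eligible presses at 2-s spacing
  expect_equal(ses$session_end, 40)
  # conservation: reward count = floor(eligible presses / 2)
  n_press <- sum(ses$events$event_type == "press")
  expect_identical(ses$n_rewards, as.integer(floor(n_press / 2)))
})

test_that("VT delivers noncontingently regardless of pressing", {
  ses <- simulate_operant_session(
    schedule_config("VT", criterion_rewards = 30, session_cap = 1e5,
                    vt_mean_interval = 60),
    numeric(0), seed = 2)
  expect_identical(ses$n_rewards, 30L + 0L)
  expect_equal(sum(ses$events$event_type == "press"), 0)
})

test_that("a silent subject on a ratio schedule runs to the cap unrewarded", {
  ses <- simulate_operant_session(
    schedule_config("FR1", criterion_rewards = 30, session_cap = 60),
    bout_process_params(bout_rate = 0, solitary_rate = 0, duration = 60,
                        seed = 1),
    seed = 1, spontaneous_magazine_rate = 0)
  expect_identical(ses$n_rewards, 0L)
  expect_equal(ses$session_end, 60)
  expect_equal(sum(ses$events$event_type == "press"), 0)
})

test_that("RI60 inter-reward intervals approach the 60-s mean", {
  ses <- simulate_operant_session(
    schedule_config("RI60", criterion_rewards = 400, session_cap = 50000),
    regular_press_times(50000), seed = 11, spontaneous_magazine_rate = 0)
  rw <- ses$events$time_s[ses$events$event_type == "reward"]
  expect_gte(length(rw), 300)
  m <- mean(diff(rw))
  expect_gt(m, 60 * 0.88)
  expect_lt(m, 60 * 1.12)
  # each reward is preceded by a lever activation at or before it
  act <- ses$events$time_s[ses$events$event_type == "lever_active"]
  expect_true(all(vapply(rw, function(r) any(act <= r & act > r - 1e4), TRUE)))
})

test_that("sessions are reproducible under a fixed seed", {
  sched <- schedule_config("FR1", criterion_rewards = 20)
  bp <- bout_process_params(1, solitary_rate = 0.5, duration = 7200, seed = 5)
  a <- simulate_operant_session(sched, bp, seed = 7)
  b <- simulate_operant_session(sched, bp, seed = 7)
  expect_identical(a$events, b$events)
})

test_that("ground-truth labels survive schedule truncation", {
  sched <- schedule_config("FR1", criterion_rewards = 15)
  bp <- bout_process_params(2, solitary_rate = 1, duration = 7200, seed = 3)
  ses <- simulate_operant_session(sched, bp, seed = 3)
  expect_length(ses$press_labels, sum(ses$events$event_type == "press"))
})
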