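test_that("inter-response intervals are successive differences", {
  expect_equal(inter_response_intervals(c(0, 2, 4)), c(2, 2))
  expect_identical(inter_response_intervals(7), numeric(0))
  expect_identical(inter_response_intervals(numeric(0)), numeric(0))
  expect_error(inter_response_intervals(c(3, 1)), "sorted")
  set.seed(1)
  t <- sort(runif(1000, 0, 3600))
  iris <- inter_response_intervals(t)
  expect_true(all(iris >= 0))
  expect_equal(sum(iris), max(t) - min(t))
})

test_that("epoch probabilities implement the discrete IRI hazard", {
  p <- epoch_response_probabilities(c(1, 3, 7, 12), bout_config())
  expect_equal(unname(p), c(2 / 4, 1 / 2, 1 / 1))
  expect_equal(unname(epoch_response_probabilities(c(0.5, 2, 4.9))), 1)
  expect_error(epoch_response_probabilities(numeric(0)), "no intervals")
})

test_that("exponential IRIs give a flat hazard at 1 - exp(-lambda w)", {
  set.seed(42)
  iris <- rexp(10000, rate = 0.2)
  p <- epoch_response_probabilities(iris, bout_config(epoch_width = 5))
  expect_equal(unname(p[1:4]), rep(1 - exp(-1), 4), tolerance = 0.04)
  # regression of the populated epochs on index: slope CI covers 0
  pop <- which(vapply(seq_along(p), function(k) sum(iris >= (k - 1) * 5) >= 200,
                      TRUE))
  fit <- lm(p[pop] ~ pop)
  ci <- confint(fit)["pop", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("bout partition splits at gaps >= threshold", {
  pt <- partition_bouts(c(0, 2, 4, 60, 100, 101), bout_config())
  expect_equal(pt$bouts, list(c(0, 2, 4), c(100, 101)))
  expect_equal(pt$solitary, 60)
  expect_equal(length(partition_bouts(10)$bouts), 0)
  expect_equal(partition_bouts(10)$solitary, 10)
  one_long <- partition_bouts(seq(0, by = 4.9, length.out = 10))
  expect_length(one_long$bouts, 1)
  expect_length(one_long$bouts[[1]], 10)
  # a gap exactly at the threshold splits
  pt2 <- partition_bouts(c(0, 5), bout_config(gap_threshold = 5))
  expect_length(pt2$bouts, 0)
  expect_equal(pt2$solitary, c(0, 5))
  expect_length(partition_bouts(numeric(0))$solitary, 0)
})

test_that("partition matches the brute-force gap-enumeration oracle", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(0:50, 1)
    times <- sort(round(runif(n, 0, 120), 2))
    times <- unique(times)
    pt <- partition_bouts(times, bout_config())
    bf <- brute_force_partition(times, 5, 2)
    expect_equal(pt$bouts, bf$bouts)
    expect_equal(pt$solitary, bf$solitary)
    # count conservation
    expect_equal(sum(lengths(pt$bouts)) + length(pt$solitary), length(times))
  }
})

test_that("run count is non-increasing in the gap threshold", {
  set.seed(21)
  times <- sort(runif(200, 0, 600))
  n_runs <- vapply(c(0.5, 1, 2, 5, 10, 30), function(thr) {
    pt <- partition_bouts(times, bout_config(gap_threshold = thr))
    length(pt$bouts) + length(pt$solitary)
  }, 1)
  expect_true(all(diff(n_runs) <= 0))
})

test_that("bout summary reports the microstructure metrics", {
  pt <- partition_bouts(c(0, 2, 4, 60, 100, 101))
  s <- bout_summary(pt, magazine_times = c(10, 20))
  expect_equal(s$bout_frequency, 2)
  expect_equal(s$bout_density, 2.5)
  expect_equal(s$n_solitary, 1)
  expect_equal(s$n_presses, 6)
  expect_equal(s$n_magazine, 2)
  # no bouts: density undefined, not zero
  s0 <- bout_summary(partition_bouts(numeric(0)))
  expect_equal(s0$bout_frequency, 0)
  expect_true(is.na(s0$bout_density))
  expect_equal(s0$n_solitary, 0)
  # median variant
  pt3 <- partition_bouts(c(0, 1, 2, 20, 21, 40, 41, 42, 43, 44))
  expect_equal(bout_summary(pt3, density = "median")$bout_density, 3)
})

test_that("summary counts equal generator ground truth under separability", {
  for (s in 1:30) {
    st <- simulate_bout_process(
      bout_process_params(1, presses_per_bout_mean = 4, solitary_rate = 0.8,
                          duration = 1800, seed = s))
    pt <- partition_bouts(st$times, bout_config())
    expect_identical(length(pt$bouts), length(st$bouts))
    expect_identical(length(pt$solitary), length(st$solitary))
    if (length(st$bouts))
      expect_equal(mean(lengths(pt$bouts)), mean(lengths(st$bouts)))
  }
})

test_that("bout-magazine correlations match the product-moment oracle", {
  mk <- function(freq, dens, sol, mag) {
    structure(list(n_presses = 0L, bout_frequency = freq, bout_density = dens,
                   n_solitary = sol, n_magazine = mag,
                   epoch_probabilities = numeric(0)),
              class = "bout_summary")
  }
  sums <- Map(mk, freq = c(1, 2, 3), dens = c(2, 2.5, 3), sol = c(0, 1, 2),
              mag = c(2, 4, 6))
  res <- correlate_bout_magazine(sums)
  expect_equal(res$r[res$metric == "bout_frequency"], 1.0)
  # zero variance in magazine counts -> undefined
  sums2 <- Map(mk, freq = c(1, 2, 3), dens = c(2, 2.5, 3), sol = c(0, 1, 2),
               mag = c(5, 5, 5))
  res2 <- correlate_bout_magazine(sums2)
  expect_true(all(!res2$defined))
  expect_true(all(is.na(res2$r)))
  # fixed 10-point table against the hand formula
  set.seed(33)
  f <- rpois(10, 12); m <- f + rpois(10, 4)
  sums3 <- Map(mk, freq = f, dens = runif(10, 2, 5), sol = rpois(10, 3),
               mag = m)
  res3 <- correlate_bout_magazine(sums3)
  expect_equal(res3$r[res3$metric == "bout_frequency"], pearson_oracle(f, m),
               tolerance = 1e-12)
  expect_error(correlate_bout_magazine(sums[1:2]), "3 animals")
})
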