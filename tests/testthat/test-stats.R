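test_that("identical samples give t = 0 and p = 1", {
  d <- data.frame(value = c(1, 2, 3, 1, 2, 3), group = rep(c("a", "b"), each = 3))
  res <- group_compare(d, "t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("t and F match independent closed-form computation", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  d <- data.frame(value = c(a, b), group = rep(c("a", "b"), each = 3))
  expect_equal(group_compare(d, "t")$statistic, welch_t_oracle(a, b),
               tolerance = 1e-10)
  expect_equal(group_compare(d, "one_way")$statistic,
               oneway_f_oracle(d$value, d$group), tolerance = 1e-10)
  set.seed(31)
  v <- rnorm(24); g <- rep(letters[1:3], each = 8)
  expect_equal(group_compare(data.frame(value = v, group = g),
                             "one_way")$statistic,
               oneway_f_oracle(v, g), tolerance = 1e-10)
})

test_that("pearson design reproduces the product-moment correlation", {
  set.seed(32)
  x <- rnorm(15); y <- x + rnorm(15)
  res <- group_compare(data.frame(value = x, value2 = y), "pearson")
  expect_equal(res$statistic, pearson_oracle(x, y), tolerance = 1e-12)
})

test_that("a planted interaction dominates the main effects", {
  # crossed pattern: group effect reverses across factor2 levels
  d <- expand.grid(rep = 1:4, group = c("g1", "g2"), factor2 = c("f1", "f2"))
  d$value <- with(d, ifelse((group == "g1") == (factor2 == "f1"), 10, 0)) +
    c(-0.2, -0.1, 0.1, 0.2)
  res <- group_compare(d, "two_way")
  an <- res$anova
  expect_gt(an$F[an$effect == "group:factor2"],
            max(an$F[an$effect %in% c("group", "factor2")]))
  expect_true(res$gated)
})

test_that("post-hoc contrasts are gated on the significant effect", {
  set.seed(33)
  d_null <- data.frame(value = rnorm(30), group = rep(letters[1:3], 10))
  res <- group_compare(d_null, "one_way")
  if (!res$gated) expect_null(res$posthoc)
  d_eff <- data.frame(value = c(rnorm(10), rnorm(10) + 5, rnorm(10)),
                      group = rep(letters[1:3], each = 10))
  res2 <- group_compare(d_eff, "one_way")
  expect_true(res2$gated)
  expect_s3_class(res2$posthoc, "data.frame")
  expect_true(all(res2$posthoc$p_adj >= res2$posthoc$p - 1e-15))
})

test_that("repeated-measures design handles the balanced two-level case only", {
  set.seed(34)
  d <- expand.grid(subject = sprintf("s%d", 1:10), factor2 = c("pre", "post"))
  d$group <- rep(rep(c("veh", "cno"), each = 5), 2)
  d$value <- rnorm(20) + ifelse(d$factor2 == "post" & d$group == "cno", 3, 0)
  res <- group_compare(d, "two_way_rm")
  expect_true(is.finite(res$statistic))
  expect_true(res$p < 0.05)
  # unbalanced: a subject observed twice in one level
  d_bad <- rbind(d, d[1, ])
  expect_error(group_compare(d_bad, "two_way_rm"), "balanced")
})

test_that("paired design matches t.test on ordered subjects", {
  set.seed(35)
  base <- rnorm(8)
  d <- data.frame(value = c(base, base + 1 + rnorm(8, 0, 0.2)),
                  group = rep(c("pre", "post"), each = 8),
                  subject = rep(sprintf("s%d", 1:8), 2))
  res <- group_compare(d, "paired_t")
  ref <- t.test(base, base + 1 + (d$value[9:16] - base - 1), paired = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("Grubbs screening removes a gross outlier and reports it", {
  d <- data.frame(value = c(10, 11, 9, 10.5, 9.5, 50,
                            10, 11, 9, 10.5, 9.5, 10),
                  group = rep(c("a", "b"), each = 6))
  res <- group_compare(d, "t", grubbs = TRUE)
  expect_equal(nrow(res$removed), 1)
  expect_equal(res$removed$value, 50)
  res_off <- group_compare(d, "t")
  expect_null(res_off$removed)
})

test_that("empty cells and missing outcomes are rejected", {
  expect_error(group_compare(data.frame(value = c(1, NA), group = c("a", "b")),
                             "t"), "missing")
  expect_error(group_compare(data.frame(value = 1:4,
                                        group = c("a", "a", "a", "a")), "t"),
               "2 groups")
})
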