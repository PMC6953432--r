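test_that("trimmed mean removes the right tails", {
  expect_equal(trimmed_mean(1:10, 0.2), 5.5)
  expect_equal(trimmed_mean(1:10, 0.2), mean(3:8))
  expect_equal(trimmed_mean(c(4, 2, 500, 1, 3, 5, 6, 7, 8, 0), 0.2),
               trimmed_mean(c(4, 2, 9, 1, 3, 5, 6, 7, 8, 0), 0.2))
  # trim 0 is the arithmetic mean; heavy trimming approaches the median
  x <- c(1, 2, 3, 4, 100)
  expect_equal(trimmed_mean(x, 0), mean(x))
  expect_equal(trimmed_mean(x, 0.45), median(x))
  expect_error(trimmed_mean(1:2, 0.5), "trim")
})

test_that("Yuen's bootstrap test behaves at its trivial endpoints", {
  x <- c(1, 5, 2, 8, 4, 6, 3, 9, 2, 7)
  r <- yuen_boot(x, x, n_boot = 200, seed = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$estimate, 0)
  expect_gt(r$p_value, 0.5)
  # strongly shifted groups are detected
  set.seed(2)
  r2 <- yuen_boot(rnorm(30), rnorm(30, 3), n_boot = 1000, seed = 3)
  expect_lt(r2$p_value, 0.01)
  expect_lt(r2$conf_int[1], -2)
  # deterministic under fixed seed, regardless of ambient RNG state
  set.seed(6)
  a <- rnorm(20); b <- rnorm(20, 1)
  r3 <- yuen_boot(a, b, n_boot = 500, seed = 5)
  set.seed(99)
  r4 <- yuen_boot(a, b, n_boot = 500, seed = 5)
  expect_identical(r3$p_value, r4$p_value)
  expect_identical(r3$conf_int, r4$conf_int)
  # degenerate constant groups are flagged, not crashed
  rd <- yuen_boot(rep(2, 10), rep(2, 10), seed = 1)
  expect_equal(rd$p_value, 1)
})

test_that("Yuen's statistic matches a hand-computed small case", {
  # n = 5, trim 0.2 -> g = 1, h = 3
  x <- c(1, 2, 3, 4, 100)
  y <- c(0, 1, 2, 3, 4)
  tmx <- mean(c(2, 3, 4))          # 3
  wx <- c(1, 2, 3, 4, 4); wx[1] <- 2  # winsorized: 2,2,3,4,4
  swx <- var(c(2, 2, 3, 4, 4))
  tmy <- mean(c(1, 2, 3))
  swy <- var(c(1, 1, 2, 3, 3))
  dx <- 4 * swx / (3 * 2); dy <- 4 * swy / (3 * 2)
  expect_equal(neonosc:::.yuen_stat(x, y, 0.2)$stat,
               (tmx - tmy) / sqrt(dx + dy))
})

test_that("the paired test works on difference scores", {
  set.seed(4)
  x <- rnorm(20)
  r <- yuen_paired(x, x, n_boot = 200, seed = 1)
  expect_equal(r$p_value, 1)
  y <- x + 5 + rnorm(20, 0, 0.1)
  r2 <- yuen_paired(y, x, n_boot = 1000, seed = 2)
  expect_lt(r2$p_value, 0.01)
  expect_equal(r2$estimate, 5, tolerance = 0.2)
  # jointly permuting pairs leaves the statistic unchanged
  perm <- sample(20)
  r3 <- yuen_paired(y[perm], x[perm], n_boot = 1000, seed = 2)
  expect_equal(r2$statistic, r3$statistic)
  expect_error(yuen_paired(x, x[1:10]), "equal-length")
})

test_that("trimmed-means ANOVA separates shifted groups only", {
  g_same <- list(c(1, 5, 2, 8, 4, 6, 3, 9, 2, 7),
                 c(1, 5, 2, 8, 4, 6, 3, 9, 2, 7),
                 c(1, 5, 2, 8, 4, 6, 3, 9, 2, 7))
  r <- t1way_boot(g_same, n_boot = 500, seed = 1)
  expect_gt(r$p_value, 0.5)
  set.seed(5)
  g_diff <- list(rnorm(20), rnorm(20), rnorm(20, 2))
  r2 <- t1way_boot(g_diff, n_boot = 1000, seed = 2, posthoc = TRUE)
  expect_lt(r2$p_value, 0.01)
  expect_equal(nrow(r2$posthoc), 3)
  # the shifted pairwise contrasts exclude zero
  shifted <- r2$posthoc[r2$posthoc$group_2 == 3 | r2$posthoc$group_1 == 3, ]
  expect_true(all(shifted$ci_lo > 0 | shifted$ci_hi < 0))
  expect_error(t1way_boot(list(rnorm(10))), "2 groups")
})

test_that("discrimination ratios follow the interaction-time formula", {
  expect_equal(discrimination_ratio(10, 10), 0)
  expect_equal(discrimination_ratio(10, 0), 1)
  expect_equal(discrimination_ratio(30, 10), 0.5)
  expect_equal(discrimination_ratio(c(30, 10), c(10, 30)), c(0.5, -0.5))
  expect_true(is.na(discrimination_ratio(0, 0)))
  expect_error(discrimination_ratio(-1, 2), ">= 0")
})

test_that("robust test results are tidy-able", {
  r <- yuen_boot(rnorm(15), rnorm(15, 1), n_boot = 200, seed = 8)
  td <- tidy(r)
  expect_equal(td$p.value, r$p_value)
  expect_equal(glance(r)$n.boot, 200)
})
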