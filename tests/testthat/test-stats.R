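fake_measurements <- function(widths, offsets = c(-2, -1, 0, 1, 2),
                              levels = c("crestal", "-2.5mm", "-5.0mm")) {
  grid <- expand.grid(offset_mm = offsets, depth_level = levels,
                      stringsAsFactors = FALSE)
  data.frame(grid, slice_index = 1L, width_mm = widths,
             peak_left_mm = 0, peak_right_mm = widths, flags = "")
}

test_that("width change uses the loss sign convention and keeps gaps explicit", {
  t0 <- fake_measurements(rep(7.0, 15))
  t1 <- fake_measurements(rep(7.0, 15))
  ch <- width_change(t0, t1)
  expect_true(all(ch$loss_mm == 0))

  t1$width_mm[3] <- 7.5   # gain at one position
  t1$width_mm[5] <- NA    # unmeasurable at follow-up
  ch <- width_change(t0, t1)
  expect_equal(ch$loss_mm[3], -0.5)
  expect_true(is.na(ch$loss_mm[5]))
  expect_identical(nrow(ch), 15L)

  bad <- t1[-1, ]
  expect_error(width_change(t0, bad), "mismatch")
})

test_that("width change pairs positions by label, not by row order", {
  t0 <- fake_measurements(1:15)
  t1 <- fake_measurements(1:15 + 0.5)
  ch0 <- width_change(t0, t1)
  ch1 <- width_change(t0, t1[sample(15), ])
  expect_equal(ch1, ch0)
})

test_that("per-position summaries use the n-1 SD and report degenerate cells honestly", {
  rec <- do.call(rbind, lapply(1:3, function(s)
    data.frame(scan_pair_id = s,
               offset_mm = 0, depth_level = "crestal", loss_mm = s)))
  s <- summarize_positions(rec)
  expect_equal(s$mean, 2)   # {1,2,3}
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3L)

  one <- summarize_positions(rec[1, ])
  expect_true(is.na(one$sd))
  gone <- rec; gone$loss_mm <- NA
  expect_identical(summarize_positions(gone)$n, 0L)
})

test_that("one-way ANOVA and Tukey HSD match the closed-form oracle", {
  # identical groups: F ~ 0, all Tukey p ~ 1
  null <- anova_tukey(rep(c(1, 2, 3), 3), rep(letters[1:3], each = 3))
  expect_lt(null$anova$F, 1e-20)
  expect_true(all(null$tukey$p_adj > 1 - 1e-10))

  # groups {1,2,3}, {1,2,3}, {11,12,13}: hand computation
  vals <- c(1, 2, 3, 1, 2, 3, 11, 12, 13)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- anova_tukey(vals, grp)
  means <- tapply(vals, grp, mean)           # 2, 2, 12
  mse <- 1                                   # within variance of each group
  msb <- 3 * sum((means - mean(vals))^2) / 2
  expect_equal(res$anova$F, msb / mse)
  expect_equal(res$anova$p, pf(msb / mse, 2, 6, lower.tail = FALSE))
  # studentized-range oracle for each pair
  for (i in seq_len(nrow(res$tukey))) {
    d <- abs(res$tukey$diff[i])
    p_exp <- ptukey(d / sqrt(mse / 3), 3, 6, lower.tail = FALSE)
    expect_equal(res$tukey$p_adj[i], p_exp, tolerance = 1e-8)
  }
  expect_equal(sum(res$tukey$p_adj < 0.05), 2L)  # only pairs involving c

  expect_error(anova_tukey(1:3, c("a", "a", "b")), "two observations")
  expect_error(anova_tukey(1:3, rep("a", 3)), "two groups")
})

test_that("ICC forms match a direct variance-component computation", {
  # oracle: sums of squares written out from first principles
  icc_oracle <- function(m) {
    n <- nrow(m); k <- ncol(m); g <- mean(m)
    msr <- sum((rowMeans(m) - g)^2) * k / (n - 1)
    msc <- sum((colMeans(m) - g)^2) * n / (k - 1)
    mse <- (sum((m - g)^2) - (n - 1) * msr - (k - 1) * msc) /
      ((n - 1) * (k - 1))
    list(r2_1 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
         r3_1 = (msr - mse) / (msr + (k - 1) * mse),
         r2_k = (msr - mse) / (msr + (msc - mse) / n),
         r3_k = (msr - mse) / msr)
  }
  set.seed(77)
  for (i in 1:10) {
    m <- matrix(rnorm(5 * 3, mean = 7), 5, 3)
    res <- icc(m)
    o <- icc_oracle(m)
    expect_equal(res$icc_single_random, o$r2_1)
    expect_equal(res$icc_single_fixed, o$r3_1)
    expect_equal(res$icc_average_random, o$r2_k)
    expect_equal(res$icc_average_fixed, o$r3_k)
  }
})

test_that("ICC behaves correctly in the canonical agreement scenarios", {
  # identical raters: all forms 1
  m <- cbind(c(4, 5, 6, 7), c(4, 5, 6, 7))
  res <- icc(m)
  expect_equal(res$icc_single_random, 1)
  expect_equal(res$icc_single_fixed, 1)

  # constant offset: consistency perfect, absolute agreement degraded
  m2 <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4) + 0.5)
  res2 <- icc(m2)
  expect_equal(res2$icc_single_fixed, 1)
  expect_lt(res2$icc_single_random, 1)
  expect_gt(res2$icc_single_random, 0)

  # zero between-subject variance: ICC <= 0 region reported as computed
  m3 <- cbind(c(5, 5, 5, 5), c(4, 6, 4, 6))
  expect_lte(icc(m3)$icc_single_fixed, 0)

  expect_error(icc(matrix(1:4, 4, 1)), ">= 2")
})

test_that("3D rater studies yield inter- and intra-rater ICCs", {
  set.seed(5)
  true_w <- rnorm(6, mean = 7, sd = 1.5)       # six scans
  arr <- array(0, c(6, 2, 3))                  # 2 raters x 3 repeats
  for (r in 1:2) for (p in 1:3)
    arr[, r, p] <- true_w + rnorm(6, sd = 0.1)
  res <- icc(arr)
  expect_gt(res$icc_single_random, 0.9)
  expect_length(res$intra_rater, 2L)
  expect_gt(res$intra_rater$rater1$estimate, 0.9)
  expect_lt(res$p, 0.001)
})

test_that("Bland-Altman identities hold on random inputs and flag outliers", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    r1 <- rnorm(n, 7, 1.5); r2 <- r1 + rnorm(n, 0, 0.2)
    ba <- bland_altman(r1, r2)
    d <- r1 - r2
    expect_equal(ba$mean_diff, mean(d))
    expect_equal(ba$sd_diff, sd(d))
    expect_equal(ba$upper_loa, mean(d) + 1.96 * sd(d))
    expect_equal(ba$lower_loa, mean(d) - 1.96 * sd(d))
    expect_identical(ba$outliers,
                     which(d > ba$upper_loa | d < ba$lower_loa))
  }

  # identity and constant-shift cases
  ba0 <- bland_altman(1:5, 1:5)
  expect_equal(ba0$mean_diff, 0); expect_equal(ba0$sd_diff, 0)
  expect_length(ba0$outliers, 0L)
  bas <- bland_altman(1:5, 1:5 + 0.1)
  expect_equal(bas$mean_diff, -0.1); expect_equal(bas$sd_diff, 0)

  # hand-computed example
  d <- c(-0.2, 0, 0.2, 1.0)
  bah <- bland_altman(d, rep(0, 4))
  expect_equal(bah$mean_diff, 0.25)
  expect_equal(bah$sd_diff, sd(d))
  expect_identical(bah$outliers, if (1.0 > 0.25 + 1.96 * sd(d)) 4L else integer())

  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("t-test sample size matches power.t.test and is monotone", {
  # independent oracle: stats::power.t.test solves the same noncentral-t
  # power equation continuously; our integer answer is its ceiling
  for (d in c(0.3, 0.5, 0.8, 1.019, 1.5)) {
    n_cont <- power.t.test(delta = d, sd = 1, sig.level = 0.05,
                           power = 0.80)$n
    expect_identical(sample_size_ttest(d)$n_per_group,
                     as.integer(ceiling(n_cont - 1e-9)))
  }
  expect_identical(sample_size_ttest(0.5)$n_per_group, 64L)
  expect_gt(sample_size_ttest(1.019, power = 0.95)$n_per_group, 17L)
  expect_lte(sample_size_ttest(1.2)$n_per_group,
             sample_size_ttest(1.0)$n_per_group)
  expect_lte(sample_size_ttest(1.0, alpha = 0.10)$n_per_group,
             sample_size_ttest(1.0, alpha = 0.01)$n_per_group)
  expect_error(sample_size_ttest(0), "> 0")
  expect_error(sample_size_ttest(1, alpha = 1.2), "alpha")
})
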