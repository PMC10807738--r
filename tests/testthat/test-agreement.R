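# independent oracle: ICC(A,1) from a stats::aov two-way ANOVA table
icc_a1_oracle <- function(x, y) {
  n <- length(x)
  df <- data.frame(v = c(x, y),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  tab <- anova(stats::aov(v ~ subj + rater, data = df))
  msb <- tab["subj", "Mean Sq"]
  msj <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- 2
  (msb - mse) / (msb + (k - 1) * mse + k * (msj - mse) / n)
}

test_that("ICC matches the ANOVA oracle on seeded paired samples", {
  set.seed(123)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 10, 3)
    y <- 0.8 * x + rnorm(n, sample(c(0, 1), 1), runif(1, 0.1, 4))
    res <- icc_absolute_agreement(x, y)
    expect_equal(res$icc, icc_a1_oracle(x, y), tolerance = 1e-10)
    expect_lte(res$ci[1], res$icc + 1e-12)
    expect_gte(res$ci[2], res$icc - 1e-12)
  }
})

test_that("ICC limiting cases behave as agreement demands", {
  x <- c(3.1, 4.2, 5.0, 6.7, 2.2)
  # identical nonconstant vectors: exactly 1
  res <- icc_absolute_agreement(x, x)
  expect_identical(res$icc, 1)
  expect_equal(res$ci, c(1, 1))
  # large independent noise drives agreement below 0.5, still oracle-exact
  set.seed(7)
  xx <- rnorm(30); yy <- xx + rnorm(30, 0, 10)
  res2 <- icc_absolute_agreement(xx, yy)
  expect_lt(res2$icc, 0.5)
  expect_equal(res2$icc, icc_a1_oracle(xx, yy), tolerance = 1e-10)
  # anti-agreement is negative
  z <- c(1, 2, 3, 4.5)
  expect_lt(icc_absolute_agreement(z, -z)$icc, 0)
  # zero total variance is an error, not NaN
  expect_error(icc_absolute_agreement(rep(2, 5), rep(2, 5)), "zero total variance")
  expect_error(icc_absolute_agreement(1:2, 1:2), "at least 3")
  # affine rescaling of BOTH vectors preserves ICC; of one vector does not
  a <- rnorm(20); b <- a + rnorm(20, 0, 0.3)
  expect_equal(icc_absolute_agreement(2 * a + 5, 2 * b + 5)$icc,
               icc_absolute_agreement(a, b)$icc, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(icc_absolute_agreement(a, 3 * b)$icc,
                                icc_absolute_agreement(a, b)$icc)))
  # average-measures ICC is at least the single-measures ICC here
  expect_gte(icc_absolute_agreement(a, b, measures = "average")$icc,
             icc_absolute_agreement(a, b)$icc)
})

test_that("Bland-Altman limits follow the closed formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(bland_altman(x, x)$mean_diff, 0)
  expect_equal(bland_altman(x, x)$loa_lower, 0)
  # constant offset: mean difference c, zero SD
  ba <- bland_altman(x + 0.7, x)
  expect_equal(ba$mean_diff, 0.7)
  expect_equal(ba$sd_diff, 0)
  # seeded Gaussian differences match the direct formula
  set.seed(11)
  xx <- rnorm(200); yy <- xx - rnorm(200, 0.3, 1.2)
  d <- xx - yy
  ba2 <- bland_altman(xx, yy)
  expect_equal(ba2$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(ba2$loa_upper, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba2$loa_lower, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  # limits contain >= 90% of differences on a large Gaussian sample
  inside <- d >= ba2$loa_lower & d <= ba2$loa_upper
  expect_gte(mean(inside), 0.9)
})

test_that("mean absolute error and the bundled summary are consistent", {
  expect_equal(mean_absolute_error(c(1, 2), c(1, 2)),
               list(mae = 0, sd_ae = 0, n = 2L))
  expect_equal(mean_absolute_error(c(1, 0), c(0, 1))$mae, 1)
  expect_equal(mean_absolute_error(c(1, 0), c(0, 1))$sd_ae, 0)
  set.seed(3)
  x <- rnorm(25); y <- rnorm(25)
  m <- mean_absolute_error(x, y)
  expect_equal(m$mae, mean(abs(x - y)))
  expect_equal(m$sd_ae, sd(abs(x - y)))
  s <- agreement_summary(x, y)
  expect_equal(s$mae, m$mae)
  expect_equal(s$icc, icc_absolute_agreement(x, y)$icc)
  expect_equal(s$loa[2] - s$mean_diff, 1.96 * s$sd_diff, tolerance = 1e-12)
})
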