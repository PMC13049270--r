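test_that("age regression recovers an exact linear trend and matches normal equations", {
  ages <- c(23, 31, 44, 58, 67, 75)
  d <- tibble::tibble(age = ages, mean_tcf = 300 - 1.26 * ages)
  res <- suppressWarnings(age_regression(d)) # exact line: lm warns about a perfect fit
  expect_equal(res$slope, -1.26, tolerance = 1e-12)
  expect_equal(res$intercept, 300, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$r_squared, 1)

  # noisy case against the closed-form normal-equation oracle
  set.seed(4)
  y <- 250 - 0.8 * ages + rnorm(length(ages), 0, 5)
  slope_oracle <- sum((ages - mean(ages)) * (y - mean(y))) / sum((ages - mean(ages))^2)
  res2 <- age_regression(tibble::tibble(age = ages, mean_tcf = y))
  expect_equal(res2$slope, slope_oracle, tolerance = 1e-10)
})

test_that("age regression flags degenerate inputs", {
  ages <- c(20, 40, 60)
  res <- age_regression(tibble::tibble(age = ages, mean_tcf = rep(200, 3)))
  expect_equal(res$slope, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$flag, "constant")
  expect_error(age_regression(tibble::tibble(age = c(20, 20, 20),
                                             mean_tcf = c(1, 2, 3))),
               "distinct ages")
})

test_that("age regression fits independently per region", {
  ages <- c(25, 35, 45, 55, 65)
  d <- dplyr::bind_rows(
    tibble::tibble(region = "cp", age = ages, mean_tcf = 400 - 2.91 * ages),
    tibble::tibble(region = "limbic", age = ages, mean_tcf = 280 - 1.26 * ages)
  )
  res <- suppressWarnings(age_regression(d, region = region))
  expect_equal(res$slope[res$region == "cp"], -2.91, tolerance = 1e-10)
  expect_equal(res$slope[res$region == "limbic"], -1.26, tolerance = 1e-10)
})

test_that("ICC(2,1) matches the two-way ANOVA mean-squares oracle", {
  # small hand table: 4 units x 2 sessions
  m <- rbind(c(9, 10), c(6, 5), c(8, 9), c(2, 4))
  d <- tibble::tibble(
    unit = rep(letters[1:4], each = 2),
    session = rep(1:2, times = 4),
    value = as.numeric(t(m))
  )
  # oracle: mean squares from stats::aov, Shrout-Fleiss formula assembled
  # independently of the implementation
  aovfit <- summary(stats::aov(value ~ factor(unit) + factor(session), data = d))[[1]]
  msr <- aovfit["factor(unit)", "Mean Sq"]
  msc <- aovfit["factor(session)", "Mean Sq"]
  mse <- aovfit["Residuals", "Mean Sq"]
  n <- 4; k <- 2
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  res <- icc_two_session(d)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-12)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
  # consistency variant oracle
  res3 <- icc_two_session(d, type = "consistency")
  expect_equal(res3$icc, (msr - mse) / (msr + (k - 1) * mse), tolerance = 1e-12)
})

test_that("ICC edge cases: perfect agreement, independence, pooled invariance", {
  d <- tibble::tibble(unit = rep(1:6, each = 2), session = rep(1:2, 6),
                      value = rep(c(3, 7, 1, 9, 5, 2), each = 2))
  res <- icc_two_session(d)
  expect_equal(res$icc, 1)
  expect_equal(res$ci_low, 1)

  # independent sessions: ICC near zero, inside its own CI
  set.seed(31)
  n <- 400
  d2 <- tibble::tibble(unit = rep(seq_len(n), each = 2),
                       session = rep(1:2, n),
                       value = rnorm(2 * n))
  res2 <- icc_two_session(d2)
  expect_lt(abs(res2$icc), 0.15)
  expect_true(res2$ci_low <= res2$icc && res2$icc <= res2$ci_high)

  # absolute-agreement ICC is invariant to a shared affine rescaling
  d3 <- tibble::tibble(unit = rep(1:8, each = 2), session = rep(1:2, 8),
                       value = c(1, 2, 4, 3, 6, 7, 2, 2, 9, 8, 5, 6, 3, 4, 7, 6))
  a <- icc_two_session(d3)$icc
  d3$value <- 10 + 2.5 * d3$value
  b <- icc_two_session(d3)$icc
  expect_equal(a, b, tolerance = 1e-12)
  expect_true(a >= -1 && a <= 1)

  expect_error(icc_two_session(tibble::tibble(unit = c(1, 1, 2),
                                              session = c(1, 2, 1),
                                              value = 1:3)),
               "unpaired|exactly once")
})

test_that("Bland-Altman matches its closed form and is antisymmetric", {
  d <- tibble::tibble(unit = rep(1:5, each = 2), session = rep(1:2, 5),
                      value = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5))
  res <- bland_altman(d)
  expect_equal(res$bias, 0)
  expect_equal(res$loa_low, 0)
  expect_equal(res$loa_high, 0)

  # normal-model closed form at large n
  set.seed(17)
  n <- 1e4
  s1 <- rnorm(n, 10, 2)
  d2 <- tibble::tibble(unit = rep(seq_len(n), 2),
                       session = rep(1:2, each = n),
                       value = c(s1, s1 + rnorm(n, 0.5, 1)))
  res2 <- bland_altman(d2)
  expect_equal(res2$bias, 0.5, tolerance = 0.05)
  expect_equal(res2$loa_low, 0.5 - 1.96, tolerance = 0.08)
  expect_equal(res2$loa_high, 0.5 + 1.96, tolerance = 0.08)
  # LoA width is exactly 2 * 1.96 * SD of the differences
  expect_equal(res2$loa_high - res2$loa_low, 2 * 1.96 * res2$sd_diff)

  # swapping session order negates the bias and mirrors the limits
  d3 <- d2
  d3$session <- ifelse(d3$session == 1, 2, 1)
  res3 <- bland_altman(d3)
  expect_equal(res3$bias, -res2$bias)
  expect_equal(res3$loa_low, -res2$loa_high)
  expect_equal(res3$loa_high, -res2$loa_low)
})

test_that("reproducibility plots build", {
  d <- tibble::tibble(unit = rep(1:10, each = 2), session = rep(1:2, 10),
                      value = rnorm(20, 100, 10))
  expect_s3_class(plot_bland_altman(d), "ggplot")
  ages <- tibble::tibble(age = c(25, 40, 60, 70), mean_tcf = c(250, 230, 200, 190))
  expect_s3_class(plot_age_trend(ages), "ggplot")
})
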