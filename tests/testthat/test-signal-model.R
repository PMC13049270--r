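test_that("total saturation time reproduces the protocol timings", {
  # full train and the shortened trains used for the buildup measurement
  cases <- data.frame(n = c(50, 7, 14, 27, 40, 1),
                      expected_ms = c(3725, 500, 1025, 2000, 2975, 50))
  for (i in seq_len(nrow(cases))) {
    sch <- saturation_scheme(n_pulses = cases$n[i], pulse_width_ms = 50,
                             interpulse_delay_ms = 25)
    expect_identical(total_saturation_time(sch), cases$expected_ms[i])
  }
  expect_equal(t_sat_seconds(saturation_scheme()), 3.725)
})

test_that("tissue MT buildup is monotone with asymptote alpha", {
  p <- protocol_params()
  # printed buildup value at the full train
  expect_equal(round(delta_z_tissue(p, protocol_t_sat), 2), 0.42)
  expect_equal(delta_z_tissue(p, 0), 0)
  expect_equal(delta_z_tissue(p, 1e6), p$alpha)
  tt <- seq(0.1, 10, length.out = 50)
  expect_true(all(diff(delta_z_tissue(p, tt)) > 0))
  expect_error(delta_z_tissue(p, -1), "non-negative")
})

test_that("forward model reproduces the choroid-plexus delta-Z and is linear in TCF", {
  p <- protocol_params()
  dz <- misl_forward(p, tcf = 288, t_sat_s = protocol_t_sat)
  expect_equal(dz, 0.0447, tolerance = 2e-3)
  expect_equal(misl_forward(p, 0, protocol_t_sat), 0)
  # linearity and t_sat monotonicity across random parameter draws
  set.seed(11)
  for (i in 1:20) {
    pr <- misl_params(alpha = runif(1, 0.1, 0.9),
                      r1rho_tissue = runif(1, 0.3, 5),
                      r1_csf = runif(1, 0.1, 0.5))
    tcf <- runif(1, 10, 600)
    t1 <- runif(1, 0.2, 2); t2 <- t1 + runif(1, 0.5, 4)
    expect_equal(misl_forward(pr, 2 * tcf, protocol_t_sat),
                 2 * misl_forward(pr, tcf, protocol_t_sat), tolerance = 1e-12)
    expect_lt(misl_forward(pr, tcf, t1), misl_forward(pr, tcf, t2))
  }
  # infinite-time asymptote: alpha * TCF / (6000 * R1csf)
  t_inf <- 100 / p$r1_csf
  expect_equal(misl_forward(p, 288, t_inf),
               p$alpha * 288 / (6000 * p$r1_csf), tolerance = 1e-6)
})

test_that("inversion reproduces printed group TCF values and round-trips exactly", {
  p <- protocol_params()
  # printed group-mean pairs; discrepancy up to ~1-2% expected because the
  # published values averaged per-subject alpha
  pairs <- data.frame(dz = c(0.0447, 0.0370, 0.0362, 0.0836),
                      tcf = c(288, 239, 234, 543))
  got <- tcf_from_delta_z(p, pairs$dz, protocol_t_sat)
  expect_equal(got, pairs$tcf, tolerance = 0.02)
  expect_equal(got[1], 288, tolerance = 5e-3) # CP to 3 significant figures
  expect_equal(tcf_from_delta_z(p, 0, protocol_t_sat), 0)

  set.seed(21)
  for (i in 1:20) {
    pr <- misl_params(alpha = runif(1, 0.1, 0.9),
                      r1rho_tissue = runif(1, 0.3, 5),
                      r1_csf = runif(1, 0.1, 0.5))
    tcf <- runif(1, 1, 800)
    ts <- runif(1, 0.5, 6)
    rt <- tcf_from_delta_z(pr, misl_forward(pr, tcf, ts), ts)
    expect_equal(rt, tcf, tolerance = 1e-10)
  }
})

test_that("negative delta-Z is inverted as-is and flagged, never clamped", {
  p <- protocol_params()
  expect_warning(out <- tcf_from_delta_z(p, c(-0.01, 0.02), protocol_t_sat),
                 "negative")
  expect_lt(out[1], 0)
  expect_silent(tcf_from_delta_z(p, -0.01, protocol_t_sat, flag_negative = FALSE))
})

test_that("degenerate R1app limit matches a numeric two-sided extrapolation", {
  # oracle: evaluate the exact bracket at R1app = +/-1e-6 and average,
  # cancelling the linear term
  r <- 0.23; t <- protocol_t_sat; eps <- 1e-6
  bracket_exact <- function(r1rho) {
    app <- r1rho - r
    1 + exp(-r1rho * t) * r / app - exp(-r * t) * r1rho / app
  }
  oracle <- (bracket_exact(r + eps) + bracket_exact(r - eps)) / 2
  got <- misl:::misl_bracket(r + 1e-9, r, t)
  expect_equal(got, oracle, tolerance = 1e-8)
  # at the switch point the series path agrees with the exact formula
  app <- 0.99e-4
  expect_equal(misl:::misl_bracket(r + app, r, t), bracket_exact(r + app),
               tolerance = 1e-10)
})

test_that("saturation-curve fit recovers generating parameters", {
  tt <- protocol_t_sat_series
  curve <- tibble::tibble(t_sat_s = tt, delta_z = 0.42 * (1 - exp(-1.72 * tt)))
  fit <- fit_saturation_curve(curve)
  expect_equal(fit$alpha, 0.42, tolerance = 1e-3)
  expect_equal(fit$r1rho_tissue, 1.72, tolerance = 1e-3)
  td <- tidy(fit)
  expect_identical(td$term, c("alpha", "r1rho_tissue"))
  gl <- glance(fit)
  expect_gt(gl$r.squared, 0.999)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("fit rejects degenerate and under-determined curves", {
  expect_error(
    fit_saturation_curve(tibble::tibble(t_sat_s = c(1, 2, 3), delta_z = rep(0.3, 3))),
    "unidentifiable"
  )
  expect_error(
    fit_saturation_curve(tibble::tibble(t_sat_s = c(1, 2), delta_z = c(0.1, 0.2))),
    "At least 3"
  )
  expect_error(
    fit_saturation_curve(tibble::tibble(t_sat_s = c(1, 1.5, 2), delta_z = c(0.1, 0.15, 0.2))),
    "factor of 3"
  )
})

test_that("fit is unbiased under measurement noise (Monte Carlo)", {
  set.seed(99)
  tt <- protocol_t_sat_series
  truth <- c(alpha = 0.30, r1rho = 1.0)
  clean <- truth["alpha"] * (1 - exp(-truth["r1rho"] * tt))
  est <- t(vapply(1:200, function(i) {
    z <- clean + rnorm(length(tt), 0, 0.005)
    coef(fit_saturation_curve(tibble::tibble(t_sat_s = tt, delta_z = z)))
  }, c(alpha = 0, r1rho_tissue = 0)))
  expect_equal(mean(est[, "alpha"]), 0.30, tolerance = 0.02)
  expect_equal(mean(est[, "r1rho_tissue"]), 1.0, tolerance = 0.02)
})
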