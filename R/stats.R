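#' Linear age trend of a regional exchange metric
#'
#' Ordinary least squares of a per-subject regional metric (typically mean
#' TCF) on age, with a two-sided t-test on the slope, fitted independently
#' per region. Used to quantify the age-related decline of tissue-CSF
#' exchange (slopes in mL/100 mL/min per year when the metric is TCF).
#' No multiple-testing correction is applied across regions (raw p-values
#' are reported).
#'
#' @param data A data frame with one row per subject (and region).
#' @param value,age Columns holding the metric and the age in years
#'   (tidy-eval; defaults `mean_tcf`, `age`).
#' @param region Optional grouping column; when given, one fit per region.
#' @return A tibble with columns `region` (if grouped), `slope`,
#'   `intercept`, `p_value`, `r_squared`, `n`, `flag` (`"ok"`, or
#'   `"constant"` for a degenerate flat response, for which `slope = 0`,
#'   `p_value = 1`).
#' @examples
#' d <- tibble::tibble(age = c(25, 35, 45, 60, 72),
#'                     mean_tcf = 300 - 1.26 * c(25, 35, 45, 60, 72))
#' age_regression(d)
#' @export
age_regression <- function(data, value = mean_tcf, age = age, region = NULL) {
  stopifnot(is.data.frame(data))
  v_q <- enquo(value); a_q <- enquo(age); r_q <- enquo(region)
  one_fit <- function(df) {
    y <- eval_tidy(v_q, df)
    x <- eval_tidy(a_q, df)
    ok <- !is.na(y) & !is.na(x)
    y <- y[ok]; x <- x[ok]
    if (length(x) < 3 || length(unique(x)) < 3) {
      abort("Age regression needs at least 3 subjects with distinct ages.")
    }
    if (any(x <= 0)) abort("Ages must be positive.")
    if (var(y) == 0) {
      return(tibble::tibble(slope = 0, intercept = y[1], p_value = 1,
                            r_squared = 0, n = length(x), flag = "constant"))
    }
    fit <- lm(y ~ x)
    s <- summary(fit)
    tibble::tibble(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      p_value = s$coefficients[2, 4],
      r_squared = s$r.squared,
      n = length(x),
      flag = "ok"
    )
  }
  if (rlang::quo_is_null(r_q)) return(one_fit(data))
  data |>
    dplyr::group_by(region = !!r_q) |>
    dplyr::group_modify(~ one_fit(.x)) |>
    dplyr::ungroup()
}

# Two-way mean squares for an n-units x k-sessions complete table.
two_way_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Test-retest intraclass correlation
#'
#' Single-measure intraclass correlation between repeated sessions, pooled
#' over all measurement units (typically subject-by-ROI pairs, matching a
#' pooled test-retest design). The default is the two-way random-effects
#' absolute-agreement form ICC(2,1)
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n)`,
#' with an F-based 95% confidence interval; `type = "consistency"` gives
#' ICC(3,1). Requires a complete units-by-sessions table (unpaired rows are
#' rejected).
#'
#' @param data Long-format data frame: one row per unit and session.
#' @param value Measurement column (tidy-eval; default `value`).
#' @param unit Column(s) identifying the measurement unit; character vector
#'   of column names (default `"unit"`).
#' @param session Session column name (default `"session"`).
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with `icc`, `ci_low`, `ci_high`, `type`, `n_units`,
#'   `k_sessions`.
#' @export
icc_two_session <- function(data, value = value, unit = "unit", session = "session",
                            type = c("agreement", "consistency"),
                            conf_level = 0.95) {
  stopifnot(is.data.frame(data))
  type <- match.arg(type)
  v <- eval_tidy(enquo(value), data)
  u <- interaction(data[unit], drop = TRUE)
  s <- factor(data[[session]])
  if (anyNA(v)) abort("Missing measurements are not allowed.")
  tab <- table(u, s)
  if (any(tab != 1)) {
    abort("Each unit must appear exactly once per session (unpaired rows rejected).")
  }
  m <- tapply(v, list(u, s), mean)
  ms <- two_way_ms(m)
  n <- ms$n; k <- ms$k
  alpha <- 1 - conf_level

  if (type == "consistency") {
    icc <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    if (ms$mse == 0) {
      ci <- c(1, 1)
    } else {
      f_obs <- ms$msr / ms$mse
      fl <- f_obs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- f_obs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  } else {
    icc <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
    if (ms$mse == 0 && ms$msc == 0) {
      ci <- c(1, 1)
    } else {
      a <- (k * icc) / (n * (1 - icc))
      b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
      v_df <- (a * ms$msc + b * ms$mse)^2 /
        ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
      fl <- qf(1 - alpha / 2, n - 1, v_df)
      fu <- qf(1 - alpha / 2, v_df, n - 1)
      ci <- c(
        n * (ms$msr - fl * ms$mse) /
          (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr),
        n * (fu * ms$msr - ms$mse) /
          (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
      )
    }
  }
  tibble::tibble(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 type = if (type == "agreement") "ICC(2,1)" else "ICC(3,1)",
                 n_units = n, k_sessions = k)
}

#' Bland-Altman agreement between two sessions
#'
#' Bias (mean session-2 minus session-1 difference) and 95% limits of
#' agreement `bias +/- 1.96 * SD(differences)`, pooled over all units.
#'
#' @inheritParams icc_two_session
#' @param loa_mult Limits-of-agreement multiplier (default 1.96).
#' @return A tibble with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(data, value = value, unit = "unit", session = "session",
                         loa_mult = 1.96) {
  stopifnot(is.data.frame(data))
  v <- eval_tidy(enquo(value), data)
  u <- interaction(data[unit], drop = TRUE)
  s <- factor(data[[session]])
  if (nlevels(s) != 2) abort("Bland-Altman requires exactly two sessions.")
  tab <- table(u, s)
  if (any(tab != 1)) abort("Each unit must appear exactly once per session.")
  m <- tapply(v, list(u, s), mean)
  if (nrow(m) < 2) abort("At least 2 paired units are required.")
  d <- m[, 2] - m[, 1]
  bias <- mean(d); sd_d <- sd(d)
  tibble::tibble(bias = bias, loa_low = bias - loa_mult * sd_d,
                 loa_high = bias + loa_mult * sd_d, sd_diff = sd_d,
                 n = nrow(m))
}
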