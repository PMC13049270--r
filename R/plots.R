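#' Plot a saturation-buildup fit
#'
#' Measured tissue delta-Z points with the fitted mono-exponential buildup
#' curve.
#'
#' @param object A `misl_satfit` from [fit_saturation_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.misl_satfit <- function(object, ...) {
  grid <- tibble::tibble(t_sat_s = seq(0, max(object$data$t_sat_s) * 1.05,
                                       length.out = 200))
  grid$delta_z <- predict(object, grid$t_sat_s)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t_sat_s, y = .data$delta_z)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Saturation time (s)", y = expression(Delta * Z[tissue]),
      title = sprintf("alpha = %.3f, R1rho = %.3f 1/s",
                      object$alpha, object$r1rho_tissue)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulated Z-spectrum
#'
#' Direct-saturation fraction against offset, in percent.
#'
#' @param zspec Tibble from [z_spectrum()] (columns `offset_ppm`,
#'   `ds_fraction`).
#' @return A ggplot.
#' @export
plot_z_spectrum <- function(zspec) {
  ggplot2::ggplot(zspec, ggplot2::aes(x = .data$offset_ppm,
                                      y = 100 * .data$ds_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Offset (ppm)", y = "Direct saturation (%)") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of two sessions
#'
#' Per-unit difference against mean with the bias line and 95% limits of
#' agreement.
#'
#' @inheritParams bland_altman
#' @return A ggplot.
#' @export
plot_bland_altman <- function(data, value = value, unit = "unit",
                              session = "session", loa_mult = 1.96) {
  v <- eval_tidy(enquo(value), data)
  u <- interaction(data[unit], drop = TRUE)
  s <- factor(data[[session]])
  m <- tapply(v, list(u, s), mean)
  d <- tibble::tibble(avg = rowMeans(m), diff = m[, 2] - m[, 1])
  bias <- mean(d$diff); sd_d <- sd(d$diff)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = bias, colour = "red") +
    ggplot2::geom_hline(yintercept = bias + c(-1, 1) * loa_mult * sd_d,
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of sessions", y = "Session 2 - session 1") +
    ggplot2::theme_minimal()
}

#' Age-trend scatter with regression line
#'
#' @inheritParams age_regression
#' @return A ggplot (facetted by region when a region column is given).
#' @export
plot_age_trend <- function(data, value = mean_tcf, age = age, region = NULL) {
  v_q <- enquo(value); a_q <- enquo(age); r_q <- enquo(region)
  d <- tibble::tibble(age = eval_tidy(a_q, data), value = eval_tidy(v_q, data))
  if (!rlang::quo_is_null(r_q)) d$region <- eval_tidy(r_q, data)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "Age (years)", y = "TCF (mL/100 mL/min)") +
    ggplot2::theme_minimal()
  if (!rlang::quo_is_null(r_q)) {
    p <- p + ggplot2::facet_wrap(~region, scales = "free_y")
  }
  p
}

#' Plot an axial slice of a map
#'
#' Quick-look raster of one z-slice of a 3D map (delta-S, delta-Z or TCF).
#'
#' @param volume 3D array.
#' @param z Slice index (default: middle slice).
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_map_slice <- function(volume, z = NULL, title = NULL) {
  z <- z %||% ceiling(dim(volume)[3] / 2)
  sl <- volume[, , z]
  d <- tidyr::expand_grid(y = seq_len(ncol(sl)), x = seq_len(nrow(sl)))
  d$value <- as.numeric(sl) # column-major: x varies fastest, matching expand_grid order

  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
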