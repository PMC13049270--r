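#' Tissue MT saturation buildup
#'
#' Mono-exponential buildup of the tissue MT signal with saturation time:
#' `delta_z_tissue(t) = alpha * (1 - exp(-r1rho_tissue * t))`. The asymptote
#' is the labeling efficiency `alpha`; at the full 3.725 s train the default
#' parameters give 0.42, i.e. buildup is essentially complete.
#'
#' @param params A [misl_params()] object (only `alpha` and `r1rho_tissue`
#'   are used).
#' @param t_sat_s Saturation time(s) in seconds (>= 0); vectorized.
#' @return Tissue delta-Z fraction(s), same length as `t_sat_s`.
#' @export
delta_z_tissue <- function(params, t_sat_s) {
  stopifnot(inherits(params, "misl_params"), is.numeric(t_sat_s))
  if (any(t_sat_s < 0)) abort("`t_sat_s` must be non-negative.")
  params$alpha * (1 - exp(-params$r1rho_tissue * t_sat_s))
}

# Dimensionless bracket of the quantification model:
#   1 + exp(-r1rho t) r1csf/r1app - exp(-r1csf t) r1rho/r1app,
# with r1app = r1rho - r1csf. The singularity at r1app -> 0 is removable;
# below `eps` the bracket is evaluated by its series in r1app:
#   1 - e^{-r t}(1 + r t) + e^{-r t} r (r1app t^2/2 - r1app^2 t^3/6),  r = r1csf.
misl_bracket <- function(r1rho_tissue, r1_csf, t_sat_s, eps = 1e-4) {
  stopifnot(r1rho_tissue > 0, r1_csf > 0)
  app <- r1rho_tissue - r1_csf
  r <- r1_csf
  t <- t_sat_s
  if (abs(app) < eps) {
    er <- exp(-r * t)
    1 - er * (1 + r * t) + er * r * (app * t^2 / 2 - app^2 * t^3 / 6)
  } else {
    1 + exp(-r1rho_tissue * t) * r / app - exp(-r * t) * r1rho_tissue / app
  }
}

#' Forward MISL signal model: TCF to delta-Z
#'
#' Predicts the CSF delta-Z produced by a tissue-to-CSF flow `tcf`
#' (mL/100 mL/min) after a saturation train of duration `t_sat_s`:
#'
#' `delta_z = alpha * (tcf/6000) * (1/r1_csf) * B(t)`
#'
#' where the bracket
#' `B(t) = 1 + e^(-r1rho t) r1_csf/r1_app - e^(-r1_csf t) r1rho/r1_app` and
#' `r1_app = r1rho_tissue - r1_csf`. The constant 6000 converts
#' mL/100 mL/min into fractional CSF volume turnover per second. The model is
#' linear in `tcf` and continuous as `r1_app -> 0` (a series expansion is
#' used below `|r1_app| < 1e-4`).
#'
#' @param params A [misl_params()] object.
#' @param tcf Tissue-to-CSF flow(s) in mL/100 mL/min; vectorized.
#' @param t_sat_s Saturation time in seconds (> 0), scalar or vectorized
#'   against a scalar `tcf`.
#' @return Delta-Z fraction(s).
#' @seealso [tcf_from_delta_z()] for the exact inverse.
#' @examples
#' misl_forward(misl_params(), tcf = 288, t_sat_s = 3.725) # ~0.0447
#' @export
misl_forward <- function(params, tcf, t_sat_s) {
  stopifnot(inherits(params, "misl_params"), is.numeric(tcf), is.numeric(t_sat_s))
  if (any(t_sat_s <= 0)) abort("`t_sat_s` must be positive.")
  if (any(tcf < 0, na.rm = TRUE)) abort("`tcf` must be non-negative; invert negative delta-Z with tcf_from_delta_z().")
  br <- misl_bracket(params$r1rho_tissue, params$r1_csf, t_sat_s)
  if (any(br <= 0)) {
    abort("Model-domain violation: the quantification bracket is non-positive for these parameters.")
  }
  params$alpha * (tcf / TCF_UNIT_CONSTANT) * br / params$r1_csf
}

#' Invert the MISL signal model: delta-Z to TCF
#'
#' Exact algebraic inverse of [misl_forward()] (the model is linear in TCF):
#' `tcf = delta_z * 6000 * r1_csf / (alpha * B(t))`. Negative delta-Z values
#' produce negative TCF; they are returned as-is (clamping would bias ROI
#' means) and, when `flag_negative = TRUE`, a single warning reports how many
#' were seen. `NA` propagates.
#'
#' @param params A [misl_params()] object.
#' @param delta_z Delta-Z fraction(s); vectorized.
#' @param t_sat_s Saturation time in seconds (> 0).
#' @param flag_negative Warn (once) if any finite `delta_z` is negative.
#' @return TCF value(s) in mL/100 mL/min.
#' @examples
#' p <- misl_params()
#' tcf_from_delta_z(p, c(0.0447, 0.0836), t_sat_s = 3.725)
#' @export
tcf_from_delta_z <- function(params, delta_z, t_sat_s, flag_negative = TRUE) {
  stopifnot(inherits(params, "misl_params"), is.numeric(delta_z), is.numeric(t_sat_s))
  if (any(t_sat_s <= 0)) abort("`t_sat_s` must be positive.")
  if (params$alpha == 0) abort("`alpha` must be positive to invert the model.")
  br <- misl_bracket(params$r1rho_tissue, params$r1_csf, t_sat_s)
  if (any(br <= 0)) {
    abort("Model-domain violation: the quantification bracket is non-positive for these parameters.")
  }
  n_neg <- sum(delta_z < 0, na.rm = TRUE)
  if (flag_negative && n_neg > 0) {
    warn(sprintf("%d negative delta-Z value(s) inverted to negative TCF (kept, not clamped).", n_neg))
  }
  delta_z * TCF_UNIT_CONSTANT * params$r1_csf / (params$alpha * br)
}

#' Fit the tissue saturation-buildup curve
#'
#' Least-squares fit of the mono-exponential buildup
#' `delta_z = alpha * (1 - exp(-r1rho * t_sat))` to a measured tissue
#' saturation curve, estimating the labeling efficiency `alpha` and the
#' rotating-frame relaxation rate `r1rho_tissue`. This is how both constants
#' are obtained from the variable-duration train acquisition (t_sat = 0.5,
#' 1.025, 2, 2.975, 3.725 s with the default protocol).
#'
#' Starting values are `alpha0 = max(delta_z)` and `r1rho0 = 1/t_half` where
#' `t_half` is the time at which the curve first crosses half its maximum;
#' the fit is bounded (`alpha` in `[0, 1]`, `r1rho` in `(0, 100]`), which
#' guarantees a convergence basin for monotone curves. Degenerate curves
#' (all delta-Z equal) are rejected as unidentifiable rather than silently
#' fitted.
#'
#' @param data A data frame with the saturation curve.
#' @param t_sat_s,delta_z Columns of `data` holding saturation time in
#'   seconds and the tissue delta-Z fraction (tidy-eval; defaults are the
#'   column names `t_sat_s` and `delta_z`).
#' @return An object of class `misl_satfit` with `tidy()`, `glance()`,
#'   `autoplot()`, `coef()` and `predict()` methods.
#' @examples
#' tt <- c(0.5, 1.025, 2, 2.975, 3.725)
#' curve <- tibble::tibble(t_sat_s = tt,
#'                         delta_z = 0.42 * (1 - exp(-1.72 * tt)))
#' fit <- fit_saturation_curve(curve)
#' coef(fit)
#' @export
fit_saturation_curve <- function(data, t_sat_s = t_sat_s, delta_z = delta_z) {
  stopifnot(is.data.frame(data))
  t <- eval_tidy(enquo(t_sat_s), data)
  z <- eval_tidy(enquo(delta_z), data)
  stopifnot(is.numeric(t), is.numeric(z), length(t) == length(z))
  if (length(t) < 3) abort("At least 3 saturation-curve points are required.")
  if (any(diff(order(t)) <= 0) || any(duplicated(t))) {
    abort("`t_sat_s` values must be distinct.")
  }
  o <- order(t)
  t <- t[o]; z <- z[o]
  if (min(t) <= 0) abort("`t_sat_s` must be positive.")
  if (max(t) / min(t) < 3) {
    abort("Saturation times must span at least a factor of 3 for R1rho to be identifiable.")
  }
  if (diff(range(z)) < .Machine$double.eps^0.5 * max(1, abs(z[1]))) {
    abort("All delta-Z values are equal: R1rho is unidentifiable from this curve.")
  }

  alpha0 <- max(z)
  t_half <- t[which(z >= alpha0 / 2)[1]]
  r1rho0 <- 1 / t_half
  df <- data.frame(t = t, z = z)
  fit <- minpack.lm::nlsLM(
    z ~ alpha * (1 - exp(-r1rho * t)),
    data = df,
    start = list(alpha = alpha0, r1rho = r1rho0),
    lower = c(alpha = 0, r1rho = 1e-6),
    upper = c(alpha = 1, r1rho = 100),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  conv <- fit$convInfo
  if (!isTRUE(conv$isConv)) {
    abort(sprintf("Saturation-curve fit did not converge: %s", conv$stopMessage))
  }
  est <- coef(fit)
  structure(
    list(
      fit = fit,
      alpha = unname(est["alpha"]),
      r1rho_tissue = unname(est["r1rho"]),
      data = tibble::tibble(t_sat_s = t, delta_z = z,
                            fitted = unname(est["alpha"] * (1 - exp(-est["r1rho"] * t)))),
      residual_norm = sqrt(sum(resid(fit)^2)),
      converged = TRUE,
      message = conv$stopMessage
    ),
    class = "misl_satfit"
  )
}

#' @export
coef.misl_satfit <- function(object, ...) {
  c(alpha = object$alpha, r1rho_tissue = object$r1rho_tissue)
}

#' @export
predict.misl_satfit <- function(object, t_sat_s = NULL, ...) {
  t <- t_sat_s %||% object$data$t_sat_s
  object$alpha * (1 - exp(-object$r1rho_tissue * t))
}

#' @export
print.misl_satfit <- function(x, ...) {
  cat(sprintf(
    "Saturation-buildup fit: alpha = %.4g, R1rho(tissue) = %.4g 1/s (residual norm %.3g, n = %d)\n",
    x$alpha, x$r1rho_tissue, x$residual_norm, nrow(x$data)
  ))
  invisible(x)
}

#' @rdname fit_saturation_curve
#' @param x A `misl_satfit` object.
#' @param ... Unused.
#' @export
tidy.misl_satfit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("alpha", "r1rho_tissue"),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname fit_saturation_curve
#' @export
glance.misl_satfit <- function(x, ...) {
  z <- x$data$delta_z
  rss <- sum((z - x$data$fitted)^2)
  tss <- sum((z - mean(z))^2)
  tibble::tibble(
    r.squared = 1 - rss / tss,
    sigma = sqrt(rss / max(1, nrow(x$data) - 2)),
    residual_norm = x$residual_norm,
    nobs = nrow(x$data),
    converged = x$converged
  )
}
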