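#' Describe an MT saturation pulse train
#'
#' A saturation scheme is the complete description of the off-resonance MT
#' labeling module: a train of `n_pulses` identical shaped RF pulses of width
#' `pulse_width_ms`, separated by `interpulse_delay_ms`, played at
#' `peak_b1_uT` peak amplitude and `offset_ppm` frequency offset. The default
#' is the human labeling protocol used throughout this package: 50
#' sinc-Gaussian pulses of 50 ms with 25 ms gaps at 3 uT and -10 ppm, i.e. a
#' total saturation time of 3.725 s.
#'
#' @param n_pulses Number of pulses in the train (>= 1).
#' @param pulse_width_ms Width of each pulse in milliseconds (> 0).
#' @param interpulse_delay_ms Gap between consecutive pulses in milliseconds
#'   (>= 0). No delay follows the final pulse.
#' @param peak_b1_uT Peak RF amplitude in microtesla (>= 0).
#' @param offset_ppm Saturation frequency offset in ppm (negative = upfield).
#' @param shape Name of the RF envelope; see [make_pulse()] for the
#'   registered shapes.
#' @return An object of class `misl_scheme`.
#' @seealso [total_saturation_time()], [make_pulse()], [simulate_saturation()]
#' @examples
#' sch <- saturation_scheme()
#' total_saturation_time(sch) # 3725 ms
#' @export
saturation_scheme <- function(n_pulses = 50, pulse_width_ms = 50,
                              interpulse_delay_ms = 25, peak_b1_uT = 3,
                              offset_ppm = -10, shape = "sincgauss") {
  stopifnot(
    length(n_pulses) == 1, n_pulses >= 1, n_pulses == as.integer(n_pulses),
    length(pulse_width_ms) == 1, pulse_width_ms > 0,
    length(interpulse_delay_ms) == 1, interpulse_delay_ms >= 0,
    length(peak_b1_uT) == 1, peak_b1_uT >= 0,
    length(offset_ppm) == 1, is.finite(offset_ppm),
    is.character(shape), length(shape) == 1
  )
  structure(
    list(
      n_pulses = as.integer(n_pulses),
      pulse_width_ms = as.numeric(pulse_width_ms),
      interpulse_delay_ms = as.numeric(interpulse_delay_ms),
      peak_b1_uT = as.numeric(peak_b1_uT),
      offset_ppm = as.numeric(offset_ppm),
      shape = shape
    ),
    class = "misl_scheme"
  )
}

#' Total saturation time of a pulse train
#'
#' The labeling module lasts from the start of the first pulse to the end of
#' the last: `n_pulses * (pulse_width + delay) - delay`; no delay trails the
#' final pulse. With the default protocol (50 pulses, 50/25 ms) this is
#' 3725 ms, and the shortened trains of 7, 14, 27, 40 pulses give 500, 1025,
#' 2000 and 2975 ms.
#'
#' @param scheme A [saturation_scheme()].
#' @return Total saturation time in milliseconds.
#' @export
total_saturation_time <- function(scheme) {
  stopifnot(inherits(scheme, "misl_scheme"))
  with(scheme, n_pulses * (pulse_width_ms + interpulse_delay_ms) - interpulse_delay_ms)
}

#' Total saturation time in seconds
#'
#' Convenience converter: the signal model works in seconds while acquisition
#' configs carry milliseconds.
#'
#' @inheritParams total_saturation_time
#' @return Total saturation time in seconds.
#' @export
t_sat_seconds <- function(scheme) total_saturation_time(scheme) / 1000

#' @export
print.misl_scheme <- function(x, ...) {
  cat(sprintf(
    "MT saturation scheme: %d x %s pulses, %g ms width, %g ms delay, %g uT peak, %g ppm\n  total saturation time: %g ms\n",
    x$n_pulses, x$shape, x$pulse_width_ms, x$interpulse_delay_ms,
    x$peak_b1_uT, x$offset_ppm, total_saturation_time(x)
  ))
  invisible(x)
}

#' MISL quantification constants
#'
#' The three constants of the MISL quantification model: the labeling
#' efficiency `alpha` (the steady-state tissue MT saturation fraction,
#' measured per subject as the tissue delta-Z at full saturation time), the
#' rotating-frame longitudinal relaxation rate of tissue water during the MT
#' train `r1rho_tissue`, and the longitudinal relaxation rate of CSF
#' `r1_csf`. Defaults are the group values used for human quantification at
#' 3 T: alpha = 0.42, R1rho = 1.72 1/s, and the literature R1 of CSF,
#' 0.23 1/s.
#'
#' The apparent rate `r1_app = r1rho_tissue - r1_csf` is always derived, never
#' stored; it may approach zero, in which case the model switches to a series
#' expansion (see [misl_forward()]).
#'
#' @param alpha Labeling efficiency, a fraction in `[0, 1]`.
#' @param r1rho_tissue Tissue rotating-frame relaxation rate, 1/s (> 0).
#' @param r1_csf CSF longitudinal relaxation rate, 1/s (> 0).
#' @return An object of class `misl_params`.
#' @examples
#' p <- misl_params()
#' tcf_from_delta_z(p, 0.0447, t_sat_s = 3.725) # ~288 mL/100 mL/min
#' @export
misl_params <- function(alpha = 0.42, r1rho_tissue = 1.72, r1_csf = 0.23) {
  stopifnot(
    length(alpha) == 1, alpha >= 0, alpha <= 1,
    length(r1rho_tissue) == 1, r1rho_tissue > 0,
    length(r1_csf) == 1, r1_csf > 0
  )
  structure(
    list(alpha = as.numeric(alpha), r1rho_tissue = as.numeric(r1rho_tissue),
         r1_csf = as.numeric(r1_csf)),
    class = "misl_params"
  )
}

#' Apparent relaxation rate difference
#'
#' `r1_app = r1rho_tissue - r1_csf`, the rate difference that appears in the
#' denominator of the quantification bracket. May be arbitrarily close to
#' zero; callers must treat that as a removable singularity.
#'
#' @param params A [misl_params()] object.
#' @return The rate difference in 1/s.
#' @export
r1_app <- function(params) {
  stopifnot(inherits(params, "misl_params"))
  params$r1rho_tissue - params$r1_csf
}

#' @export
print.misl_params <- function(x, ...) {
  cat(sprintf(
    "MISL model parameters: alpha = %g, R1rho(tissue) = %g 1/s, R1(CSF) = %g 1/s (R1app = %g 1/s)\n",
    x$alpha, x$r1rho_tissue, x$r1_csf, r1_app(x)
  ))
  invisible(x)
}
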