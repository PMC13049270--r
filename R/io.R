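#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti that preserve intensities, affine and voxel
#' sizes on round trip. `read_volume_series()` reads several files and
#' refuses mismatched grids before any computation (no implicit
#' resampling anywhere in the package).
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume()`: an `RNifti` image (a numeric array with
#'   metadata).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  RNifti::readNifti(path)
}

#' @rdname read_volume
#' @param volume Numeric array (3D/4D) or RNifti image.
#' @param template Optional volume whose NIfTI metadata (affine, voxel
#'   sizes) is copied onto `volume`.
#' @export
write_volume <- function(volume, path, template = NULL) {
  img <- if (!is.null(template)) RNifti::asNifti(volume, reference = template)
         else RNifti::asNifti(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @param paths Character vector of NIfTI paths.
#' @export
read_volume_series <- function(paths) {
  vols <- lapply(paths, read_volume)
  ref <- vols[[1]]
  for (i in seq_along(vols)[-1]) {
    di <- dim(vols[[i]]); dr <- dim(ref)
    if (!identical(di[1:3], dr[1:3]) ||
        !isTRUE(all.equal(RNifti::pixdim(vols[[i]])[1:3], RNifti::pixdim(ref)[1:3],
                          tolerance = 1e-6))) {
      abort(sprintf(
        "Grid mismatch in series:\n  %s: dim %s, pixdim %s\n  %s: dim %s, pixdim %s",
        paths[1], paste(dr, collapse = "x"),
        paste(signif(RNifti::pixdim(ref), 4), collapse = "x"),
        paths[i], paste(di, collapse = "x"),
        paste(signif(RNifti::pixdim(vols[[i]]), 4), collapse = "x")
      ))
    }
  }
  vols
}

#' Read / write a tissue saturation curve
#'
#' Two-column delimited text: `t_sat_s` (seconds) and `delta_z` (fraction).
#'
#' @param path File path (whitespace/comma delimited with header).
#' @return A tibble with columns `t_sat_s`, `delta_z`.
#' @export
read_saturation_curve <- function(path) {
  d <- readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                         trim_ws = TRUE)
  if (!all(c("t_sat_s", "delta_z") %in% names(d))) {
    abort("Saturation-curve file must have columns `t_sat_s` and `delta_z`.")
  }
  tibble::as_tibble(d[, c("t_sat_s", "delta_z")])
}

#' @rdname read_saturation_curve
#' @param curve Data frame with `t_sat_s`, `delta_z`.
#' @export
write_saturation_curve <- function(curve, path) {
  readr::write_csv(curve[, c("t_sat_s", "delta_z")], path)
  invisible(path)
}

#' Read / write region tables
#'
#' CSV with the per-ROI summary columns produced by [roi_statistics()],
#' optionally prefixed by `subject`, `session` identifiers.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_region_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_region_table
#' @param table Data frame to write.
#' @export
write_region_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

# Config -------------------------------------------------------------------

#' Read / write a run configuration
#'
#' Flat YAML (or JSON, by extension) carrying the saturation scheme and
#' model parameters with unit-suffixed keys: `n_pulses`, `pulse_width_ms`,
#' `interpulse_delay_ms`, `peak_b1_uT`, `offset_ppm`, `shape`, `alpha`,
#' `r1rho_tissue_s1`, `r1_csf_s1`, plus free-form pipeline settings.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `scheme` ([saturation_scheme()]), `params`
#'   ([misl_params()]) and `extra` (any remaining keys).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config_to_objects(cfg)
}

config_to_objects <- function(cfg) {
  defaults <- saturation_scheme()
  scheme <- saturation_scheme(
    n_pulses = cfg$n_pulses %||% defaults$n_pulses,
    pulse_width_ms = cfg$pulse_width_ms %||% defaults$pulse_width_ms,
    interpulse_delay_ms = cfg$interpulse_delay_ms %||% defaults$interpulse_delay_ms,
    peak_b1_uT = cfg$peak_b1_uT %||% defaults$peak_b1_uT,
    offset_ppm = cfg$offset_ppm %||% defaults$offset_ppm,
    shape = cfg$shape %||% defaults$shape
  )
  pdef <- misl_params()
  params <- misl_params(
    alpha = cfg$alpha %||% pdef$alpha,
    r1rho_tissue = cfg$r1rho_tissue_s1 %||% pdef$r1rho_tissue,
    r1_csf = cfg$r1_csf_s1 %||% pdef$r1_csf
  )
  known <- c("n_pulses", "pulse_width_ms", "interpulse_delay_ms", "peak_b1_uT",
             "offset_ppm", "shape", "alpha", "r1rho_tissue_s1", "r1_csf_s1")
  list(scheme = scheme, params = params,
       extra = cfg[setdiff(names(cfg), known)])
}

#' @rdname read_run_config
#' @param scheme A [saturation_scheme()].
#' @param params A [misl_params()].
#' @param extra Named list of additional settings to serialize.
#' @export
write_run_config <- function(path, scheme = saturation_scheme(),
                             params = misl_params(), extra = list()) {
  cfg <- c(
    list(n_pulses = scheme$n_pulses,
         pulse_width_ms = scheme$pulse_width_ms,
         interpulse_delay_ms = scheme$interpulse_delay_ms,
         peak_b1_uT = scheme$peak_b1_uT,
         offset_ppm = scheme$offset_ppm,
         shape = scheme$shape,
         alpha = params$alpha,
         r1rho_tissue_s1 = params$r1rho_tissue,
         r1_csf_s1 = params$r1_csf),
    extra
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

# Resolved-config + log sidecar written next to every CLI output.
write_run_record <- function(outdir, scheme, params, seed = NULL, extra = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "run_config.yaml")
  write_run_config(cfg_path, scheme, params,
                   extra = c(extra, list(seed = seed)))
  log_path <- file.path(outdir, "run_log.txt")
  writeLines(c(
    sprintf("misl version: %s", as.character(packageVersion("misl"))),
    sprintf("R version: %s", R.version.string),
    sprintf("seed: %s", seed %||% "none"),
    sprintf("config: %s", basename(cfg_path))
  ), log_path)
  invisible(outdir)
}
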