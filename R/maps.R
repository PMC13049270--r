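# Volumes are plain 3D numeric arrays (or RNifti images, which are arrays);
# repeated acquisitions are 4D arrays with the repeat index last. Grids must
# match exactly: no resampling happens anywhere in this module (inputs are
# pre-aligned by contract).

grid_of <- function(x) {
  d <- dim(x)
  pd <- attr(x, "pixdim") %||% tryCatch(RNifti::pixdim(x), error = function(e) NULL)
  list(dim = d, pixdim = pd)
}

check_same_grid <- function(a, b, what = "volumes") {
  da <- dim(a); db <- dim(b)
  da3 <- da[1:3]; db3 <- db[1:3]
  if (!identical(da3, db3)) {
    abort(sprintf("Grid mismatch between %s: %s vs %s.",
                  what, paste(da3, collapse = "x"), paste(db3, collapse = "x")))
  }
  invisible(TRUE)
}

as_rep_array <- function(x) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    for (v in x) check_same_grid(v, x[[1]])
    arr <- array(0, c(d, length(x)))
    for (i in seq_along(x)) arr[, , , i] <- x[[i]]
    return(arr)
  }
  if (length(dim(x)) == 3) {
    return(array(as.numeric(x), c(dim(x), 1)))
  }
  stopifnot(length(dim(x)) == 4)
  x
}

#' Bundle repeated control/label volumes
#'
#' Validates a series of repeated control and label acquisitions: shared
#' voxel grid, equal repeat counts, non-negative intensities.
#'
#' @param control,label 4D arrays (x, y, z, repeat), lists of 3D arrays, or
#'   single 3D arrays.
#' @return An object of class `misl_series` with fields `control`, `label`
#'   (4D arrays) and `n_pairs`.
#' @export
volume_series <- function(control, label) {
  control <- as_rep_array(control)
  label <- as_rep_array(label)
  check_same_grid(control, label, "control and label series")
  if (dim(control)[4] != dim(label)[4]) {
    abort("Control and label series must have equal repeat counts.")
  }
  if (min(control, na.rm = TRUE) < 0 || min(label, na.rm = TRUE) < 0) {
    abort("Magnitude intensities must be non-negative.")
  }
  structure(list(control = control, label = label, n_pairs = dim(control)[4]),
            class = "misl_series")
}

#' Control-minus-label difference image
#'
#' Averages the control and label repeats and subtracts:
#' `delta_s = mean(control) - mean(label)`, voxelwise. This raw difference
#' image is interpretable everywhere (no division), unlike delta-Z.
#'
#' @param series A [volume_series()] (or anything accepted by it when
#'   `label` is supplied).
#' @param label Optional: if given, `series` is taken as the control series.
#' @return A list with `delta_s`, `mean_control`, `mean_label` (3D arrays).
#' @export
compute_delta_s <- function(series, label = NULL) {
  if (!inherits(series, "misl_series")) series <- volume_series(series, label)
  mc <- rowMeans(series$control, dims = 3)
  ml <- rowMeans(series$label, dims = 3)
  list(delta_s = mc - ml, mean_control = mc, mean_label = ml)
}

#' Normalized MISL difference (delta-Z) map
#'
#' `delta_z = delta_s / mean_control`, defined only inside the supplied mask
#' (CSF plus PVS) and only where the control signal clears a low-signal
#' guard; everywhere else the voxel is `NA`, never zero-filled. Outside CSF
#' the long-TE control signal is residual noise, so delta-Z there is
#' meaningless; the guard removes near-zero denominators inside the mask as
#' well.
#'
#' @param delta_s,mean_control 3D arrays from [compute_delta_s()].
#' @param mask Logical 3D array where delta-Z is meaningful (typically CSF
#'   union PVS).
#' @param low_signal_guard Minimum `mean_control` for the division. If
#'   `NULL` and `background_mask` is given, it is `5 * mad(mean_control
#'   outside brain)`; if neither is given, 0.
#' @param background_mask Logical array of voxels outside the brain used to
#'   estimate the noise floor.
#' @return A list with `delta_z` (3D array, `NA` where undefined), `defined`
#'   (logical array) and `qc` (tibble: voxel counts of mask, low-signal
#'   exclusions, negative delta-Z).
#' @export
compute_delta_z <- function(delta_s, mean_control, mask,
                            low_signal_guard = NULL, background_mask = NULL) {
  check_same_grid(delta_s, mean_control)
  check_same_grid(delta_s, mask)
  mask <- array(as.logical(mask), dim(mask))
  if (is.null(low_signal_guard)) {
    low_signal_guard <- if (!is.null(background_mask)) {
      5 * mad(mean_control[as.logical(background_mask)], center = 0)
    } else 0
  }
  low <- mask & (mean_control < low_signal_guard)
  defined <- mask & !low
  dz <- array(NA_real_, dim(delta_s))
  dz[defined] <- delta_s[defined] / mean_control[defined]
  qc <- tibble::tibble(
    n_mask = sum(mask),
    n_low_signal = sum(low),
    n_defined = sum(defined),
    n_negative = sum(dz < 0, na.rm = TRUE),
    low_signal_guard = low_signal_guard
  )
  list(delta_z = dz, defined = defined, qc = qc)
}

#' Voxelwise TCF map from a delta-Z map
#'
#' Applies [tcf_from_delta_z()] elementwise; `NA` (undefined) voxels
#' propagate. Negative delta-Z voxels produce negative TCF and are kept (see
#' the QC counts) rather than clamped, which would bias ROI means.
#'
#' @param delta_z 3D array (fractions, `NA` where undefined).
#' @param params A [misl_params()].
#' @param t_sat_s Saturation time in seconds.
#' @return A 3D array of TCF in mL/100 mL/min.
#' @export
compute_tcf_map <- function(delta_z, params, t_sat_s) {
  tcf <- tcf_from_delta_z(params, as.numeric(delta_z), t_sat_s, flag_negative = FALSE)
  array(tcf, dim(delta_z))
}

#' CSF mask from the mean control image
#'
#' Long-TE control images are bimodal — bright CSF against strongly
#' suppressed parenchyma — so a single intensity cutoff isolates CSF. The
#' cutoff is either an absolute intensity or `"otsu"` (the default), which
#' applies Otsu's rule to the brain-masked intensity histogram.
#'
#' @param mean_control 3D array.
#' @param brain_mask Logical 3D array; the CSF mask is constrained to it.
#' @param threshold `"otsu"` or an absolute intensity cutoff.
#' @return A logical 3D array with attribute `threshold` (the cutoff used)
#'   and `coverage` (fraction of brain voxels classified CSF). Errors if the
#'   mask is empty.
#' @export
make_csf_mask <- function(mean_control, brain_mask, threshold = "otsu") {
  check_same_grid(mean_control, brain_mask)
  brain_mask <- array(as.logical(brain_mask), dim(brain_mask))
  if (identical(threshold, "otsu")) {
    vals <- mean_control[brain_mask]
    rng <- range(vals)
    if (diff(rng) <= 0) abort("Cannot threshold a constant image.")
    norm <- (vals - rng[1]) / diff(rng)
    th01 <- EBImage::otsu(EBImage::Image(matrix(norm, ncol = 1)),
                          range = c(0, 1), levels = 256)
    threshold <- rng[1] + th01 * diff(rng)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  mask <- brain_mask & (mean_control > threshold)
  if (!any(mask)) abort("CSF mask is empty at this threshold.")
  attr(mask, "threshold") <- threshold
  attr(mask, "coverage") <- sum(mask) / sum(brain_mask)
  mask
}

#' Perivascular-space mask from a long-TE T2-weighted image
#'
#' Thresholds high-intensity (fluid) voxels inside the brain, labels
#' connected components in 3D, and removes components larger than
#' `max_component_size` voxels — the ventricles and subarachnoid sheets —
#' leaving only small tubular structures, which are classified as PVS.
#'
#' @param long_te_t2w 3D array, long-TE T2-weighted volume on the same grid.
#' @param brain_mask Logical 3D array.
#' @param intensity_threshold Absolute cutoff for fluid-bright voxels.
#' @param max_component_size Components above this size (voxels) are removed
#'   (default 300, tuned to 1-2 voxel radius tubes at ~1 mm resolution).
#' @param connectivity 6 (faces) or 26 (faces+edges+corners, default).
#' @return Logical 3D array; empty result is allowed with a warning.
#' @export
make_pvs_mask <- function(long_te_t2w, brain_mask, intensity_threshold,
                          max_component_size = 300, connectivity = 26) {
  check_same_grid(long_te_t2w, brain_mask)
  fluid <- array(as.logical(brain_mask), dim(brain_mask)) &
    (long_te_t2w > intensity_threshold)
  if (!any(fluid)) {
    warn("No suprathreshold voxels: PVS mask is empty.")
    return(array(FALSE, dim(long_te_t2w)))
  }
  lab <- label_components(fluid, connectivity = connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes <= max_component_size)
  pvs <- array(lab %in% keep & lab > 0, dim(long_te_t2w))
  if (!any(pvs)) warn("All suprathreshold components exceed max_component_size: PVS mask is empty.")
  pvs
}

#' Dilate ROI labels and intersect with the CSF mask
#'
#' Atlas ROIs are parenchymal; the CSF voxels exhibiting exchange sit just
#' outside them. Each label is dilated by a voxel ball of the given radius
#' and intersected with the CSF mask. Where dilations of several ROIs reach
#' the same CSF voxel, the nearest original label wins; exact distance ties
#' go to the lower label id (deterministic).
#'
#' @param roi_labels Integer 3D array (0 = unlabeled).
#' @param csf_mask Logical 3D array.
#' @param dilation_radius Ball radius in voxels (>= 0; 0 means plain
#'   intersection).
#' @return Integer 3D array of CSF-restricted labels.
#' @export
dilate_and_intersect_rois <- function(roi_labels, csf_mask, dilation_radius = 1) {
  check_same_grid(roi_labels, csf_mask)
  stopifnot(dilation_radius >= 0)
  dims <- dim(roi_labels)
  csf_mask <- array(as.logical(csf_mask), dims)
  src <- which(roi_labels > 0)
  out <- array(0L, dims)
  if (length(src) == 0) return(out)

  r <- floor(dilation_radius)
  offs <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  d2 <- rowSums(offs^2)
  offs <- offs[d2 <= dilation_radius^2, , drop = FALSE]
  d2 <- d2[d2 <= dilation_radius^2]

  co <- arrayInd(src, dims)
  labs <- as.integer(roi_labels[src])
  tgt_lin <- integer(0); tgt_lab <- integer(0); tgt_d2 <- numeric(0)
  for (i in seq_len(nrow(offs))) {
    nc <- sweep(co, 2, offs[i, ], "+")
    ok <- nc[, 1] >= 1 & nc[, 1] <= dims[1] &
          nc[, 2] >= 1 & nc[, 2] <= dims[2] &
          nc[, 3] >= 1 & nc[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- (nc[ok, 3] - 1L) * dims[1] * dims[2] + (nc[ok, 2] - 1L) * dims[1] + nc[ok, 1]
    tgt_lin <- c(tgt_lin, lin)
    tgt_lab <- c(tgt_lab, labs[ok])
    tgt_d2 <- c(tgt_d2, rep(d2[i], sum(ok)))
  }
  keep <- csf_mask[tgt_lin]
  tgt_lin <- tgt_lin[keep]; tgt_lab <- tgt_lab[keep]; tgt_d2 <- tgt_d2[keep]
  if (length(tgt_lin) == 0) return(out)
  o <- order(tgt_lin, tgt_d2, tgt_lab)
  first <- !duplicated(tgt_lin[o])
  out[tgt_lin[o][first]] <- tgt_lab[o][first]
  out
}

#' Per-ROI and composite summaries of delta-Z and TCF
#'
#' Aggregates the delta-Z and TCF maps over each ROI label and over named
#' composites (unions of ROIs), excluding undefined voxels. ROIs with no
#' valid voxel are reported with `n_voxels = 0` and `NA` summaries — missing,
#' not zero.
#'
#' @param delta_z,tcf 3D arrays (`NA` = undefined).
#' @param roi_labels Integer 3D array.
#' @param roi_names Named character vector or NULL: `c("1" = "name", ...)`.
#' @param composites Named list mapping composite name to a vector of ROI
#'   ids, or NULL.
#' @return A tibble with columns `roi_id`, `roi_name`, `composite`,
#'   `n_voxels`, `mean_dz`, `sd_dz`, `mean_tcf`, `sd_tcf`. Composite rows
#'   have `roi_id = NA` and pool voxels (so a composite mean is the
#'   voxel-count-weighted mean of its parts).
#' @export
roi_statistics <- function(delta_z, tcf, roi_labels, roi_names = NULL,
                           composites = NULL) {
  check_same_grid(delta_z, roi_labels)
  check_same_grid(delta_z, tcf)
  ids <- sort(unique(as.integer(roi_labels[roi_labels > 0])))
  summarize_vox <- function(sel) {
    dz <- delta_z[sel]; tc <- tcf[sel]
    ok <- !is.na(dz)
    tibble::tibble(
      n_voxels = sum(ok),
      mean_dz = if (any(ok)) mean(dz[ok]) else NA_real_,
      sd_dz = if (sum(ok) > 1) sd(dz[ok]) else NA_real_,
      mean_tcf = if (any(ok)) mean(tc[ok]) else NA_real_,
      sd_tcf = if (sum(ok) > 1) sd(tc[ok]) else NA_real_
    )
  }
  per_roi <- purrr::map_dfr(ids, function(id) {
    dplyr::bind_cols(
      tibble::tibble(
        roi_id = id,
        roi_name = if (!is.null(roi_names)) roi_names[[as.character(id)]] %||% as.character(id) else as.character(id),
        composite = NA_character_
      ),
      summarize_vox(roi_labels == id)
    )
  })
  per_comp <- NULL
  if (!is.null(composites)) {
    per_comp <- purrr::imap_dfr(composites, function(cids, cname) {
      dplyr::bind_cols(
        tibble::tibble(roi_id = NA_integer_, roi_name = cname, composite = cname),
        summarize_vox(array(roi_labels %in% cids, dim(roi_labels)))
      )
    })
  }
  dplyr::bind_rows(per_roi, per_comp)
}

#' Full voxelwise MISL quantification pipeline
#'
#' Runs the mapping pipeline downstream of registration: averages the
#' repeats, computes the delta-S, delta-Z (CSF/PVS-masked, low-signal
#' guarded) and TCF maps, and aggregates over ROIs. Masks gate where values
#' are defined and aggregated; stored intensities are never altered.
#'
#' @param series A [volume_series()].
#' @param params A [misl_params()].
#' @param t_sat_s Saturation time in seconds.
#' @param csf_mask Logical array, or NULL to derive with [make_csf_mask()]
#'   from the mean control and `brain_mask`.
#' @param brain_mask Logical array (required if `csf_mask` is NULL).
#' @param pvs_mask Optional logical array unioned into the defined region.
#' @param roi_labels,roi_names,composites Optional ROI aggregation inputs,
#'   see [roi_statistics()].
#' @param csf_threshold Passed to [make_csf_mask()] when deriving the mask.
#' @param low_signal_guard,background_mask Passed to [compute_delta_z()].
#' @return An object of class `misl_maps`: list with `delta_s`,
#'   `mean_control`, `delta_z`, `tcf`, `defined`, `qc`, `masks`, and
#'   `region_table` (NULL when no ROIs given).
#' @export
misl_quantify <- function(series, params, t_sat_s,
                          csf_mask = NULL, brain_mask = NULL, pvs_mask = NULL,
                          roi_labels = NULL, roi_names = NULL, composites = NULL,
                          csf_threshold = "otsu",
                          low_signal_guard = NULL, background_mask = NULL) {
  stopifnot(inherits(series, "misl_series"), inherits(params, "misl_params"))
  ds <- compute_delta_s(series)
  if (is.null(csf_mask)) {
    if (is.null(brain_mask)) abort("Supply `csf_mask` or `brain_mask`.")
    csf_mask <- make_csf_mask(ds$mean_control, brain_mask, threshold = csf_threshold)
  }
  defined_mask <- if (is.null(pvs_mask)) csf_mask else (csf_mask | pvs_mask)
  if (is.null(background_mask) && !is.null(brain_mask)) {
    background_mask <- !array(as.logical(brain_mask), dim(brain_mask))
  }
  dz <- compute_delta_z(ds$delta_s, ds$mean_control, defined_mask,
                        low_signal_guard = low_signal_guard,
                        background_mask = background_mask)
  tcf <- compute_tcf_map(dz$delta_z, params, t_sat_s)
  region_table <- NULL
  if (!is.null(roi_labels)) {
    region_table <- roi_statistics(dz$delta_z, tcf, roi_labels, roi_names, composites)
  }
  structure(
    list(delta_s = ds$delta_s, mean_control = ds$mean_control,
         delta_z = dz$delta_z, tcf = tcf, defined = dz$defined, qc = dz$qc,
         masks = list(csf = csf_mask, pvs = pvs_mask, brain = brain_mask),
         region_table = region_table,
         params = params, t_sat_s = t_sat_s),
    class = "misl_maps"
  )
}

#' @export
print.misl_maps <- function(x, ...) {
  cat(sprintf(
    "MISL maps on a %s grid: %d defined voxels (%d low-signal excluded, %d negative delta-Z)\n",
    paste(dim(x$delta_s), collapse = "x"),
    x$qc$n_defined, x$qc$n_low_signal, x$qc$n_negative
  ))
  if (!is.null(x$region_table)) {
    cat(sprintf("Region table: %d rows\n", nrow(x$region_table)))
  }
  invisible(x)
}
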