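# Geometry primitives ------------------------------------------------------

voxel_coords <- function(dims) {
  list(
    x = array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dims),
    y = array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]), dims),
    z = array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims)
  )
}

ellipsoid_mask <- function(dims, center, radii, coords = voxel_coords(dims)) {
  ((coords$x - center[1]) / radii[1])^2 +
  ((coords$y - center[2]) / radii[2])^2 +
  ((coords$z - center[3]) / radii[3])^2 <= 1
}

shell_mask <- function(dims, center, radii_outer, thickness, coords = voxel_coords(dims)) {
  outer <- ellipsoid_mask(dims, center, radii_outer, coords)
  inner <- ellipsoid_mask(dims, center, radii_outer - thickness, coords)
  outer & !inner
}

# capsule: all voxels within `radius` of the segment from `from` to `to`
tube_mask <- function(dims, from, to, radius, coords = voxel_coords(dims)) {
  v <- to - from
  len2 <- sum(v^2)
  px <- coords$x - from[1]; py <- coords$y - from[2]; pz <- coords$z - from[3]
  tt <- if (len2 == 0) array(0, dims) else (px * v[1] + py * v[2] + pz * v[3]) / len2
  tt <- pmin(pmax(tt, 0), 1)
  dx <- px - tt * v[1]; dy <- py - tt * v[2]; dz <- pz - tt * v[3]
  dx^2 + dy^2 + dz^2 <= radius^2
}

# Compartments --------------------------------------------------------------

#' Define a phantom compartment
#'
#' @param name Compartment name (also its ROI name).
#' @param geometry One of `"ellipsoid"`, `"shell"`, `"tube"`.
#' @param tcf Ground-truth tissue-to-CSF flow, mL/100 mL/min (>= 0).
#' @param intensity Control-image intensity (arbitrary units).
#' @param is_csf Whether the compartment is CSF-like (bright at long TE,
#'   subject to the direct-saturation floor).
#' @param ds_fraction Per-compartment direct-saturation override; `NA` means
#'   use the spec-level `ds_fraction` (for CSF compartments).
#' @param center,radii Ellipsoid/shell parameters (voxel units).
#' @param thickness Shell thickness (voxels).
#' @param from,to,radius Tube (capsule) parameters (voxel units).
#' @return A `misl_compartment` list.
#' @export
phantom_compartment <- function(name, geometry, tcf, intensity = 1000,
                                is_csf = TRUE, ds_fraction = NA_real_,
                                center = NULL, radii = NULL, thickness = NULL,
                                from = NULL, to = NULL, radius = NULL) {
  stopifnot(geometry %in% c("ellipsoid", "shell", "tube"), tcf >= 0, intensity >= 0)
  structure(
    list(name = name, geometry = geometry, tcf = tcf, intensity = intensity,
         is_csf = is_csf, ds_fraction = ds_fraction,
         center = center, radii = radii, thickness = thickness,
         from = from, to = to, radius = radius),
    class = "misl_compartment"
  )
}

#' Default phantom compartments
#'
#' A minimal head topology on the default 64 x 64 x 48 grid: two
#' lateral-ventricle ellipsoids, a subarachnoid shell just inside the brain
#' surface, a choroid-plexus blob inside each ventricle, four perivascular
#' tubes (radius 1.4 voxels) in deep tissue, and one zero-flow cyst used as
#' the direct-saturation control. Ground-truth TCF values mirror the human
#' group means: ventricles 100, SAS 150, choroid plexus 288, PVS 543
#' mL/100 mL/min.
#'
#' @param csf_intensity Control intensity of CSF compartments.
#' @return List of [phantom_compartment()]s (painted in order; later
#'   compartments override earlier ones where they overlap).
#' @export
default_phantom_compartments <- function(csf_intensity = 1000) {
  list(
    phantom_compartment("sas", "shell", tcf = 150, intensity = csf_intensity,
                        center = c(32, 32, 24), radii = c(27, 29, 20), thickness = 2.5),
    phantom_compartment("lateral_ventricle_left", "ellipsoid", tcf = 100,
                        intensity = csf_intensity,
                        center = c(23, 35, 25), radii = c(5, 9, 4)),
    phantom_compartment("lateral_ventricle_right", "ellipsoid", tcf = 100,
                        intensity = csf_intensity,
                        center = c(41, 35, 25), radii = c(5, 9, 4)),
    phantom_compartment("choroid_plexus_left", "ellipsoid", tcf = 288,
                        intensity = csf_intensity,
                        center = c(23, 39, 25), radii = c(2, 3, 2)),
    phantom_compartment("choroid_plexus_right", "ellipsoid", tcf = 288,
                        intensity = csf_intensity,
                        center = c(41, 39, 25), radii = c(2, 3, 2)),
    phantom_compartment("pvs_1", "tube", tcf = 543, intensity = csf_intensity,
                        from = c(26, 20, 16), to = c(26, 20, 28), radius = 1.4),
    phantom_compartment("pvs_2", "tube", tcf = 543, intensity = csf_intensity,
                        from = c(38, 20, 16), to = c(38, 20, 28), radius = 1.4),
    phantom_compartment("pvs_3", "tube", tcf = 543, intensity = csf_intensity,
                        from = c(30, 16, 28), to = c(40, 16, 32), radius = 1.4),
    phantom_compartment("pvs_4", "tube", tcf = 543, intensity = csf_intensity,
                        from = c(22, 18, 32), to = c(22, 26, 32), radius = 1.4),
    phantom_compartment("cyst", "ellipsoid", tcf = 0, intensity = csf_intensity,
                        center = c(13, 30, 24), radii = c(4, 5, 4))
  )
}

#' Specify a digital MISL phantom
#'
#' The phantom emulates the long-TE acquisition: CSF compartments are bright
#' (`intensity`), parenchyma is suppressed to `tissue_intensity` (default 2%
#' of CSF, the long-TE residual), the label condition reduces each CSF
#' compartment by the forward-model delta-Z for its ground-truth TCF plus a
#' direct-saturation floor, and magnitude noise is Rician.
#'
#' @param dims Grid dimensions (default `c(64, 64, 48)`).
#' @param vox_mm Isotropic voxel size in mm (default 2, metadata only).
#' @param compartments List of [phantom_compartment()]s.
#' @param tissue_intensity Parenchyma control intensity (default 20 = 2% of
#'   the default CSF 1000).
#' @param noise_sigma Rician sigma on each complex channel (default 20,
#'   i.e. CSF SNR 50).
#' @param n_pairs Number of control/label repeats (default 18).
#' @param ds_fraction Direct-saturation floor applied to CSF compartments in
#'   the label condition (default 0.003, the measured in-vivo cyst value).
#' @param seed Integer seed; randomness is never wall-clock derived.
#' @return A `misl_phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(64, 64, 48), vox_mm = 2,
                         compartments = default_phantom_compartments(),
                         tissue_intensity = 20, noise_sigma = 20,
                         n_pairs = 18, ds_fraction = 0.003, seed = 42) {
  stopifnot(length(dims) == 3, all(dims >= 8), n_pairs >= 1,
            noise_sigma >= 0, ds_fraction >= 0, ds_fraction < 1,
            is.numeric(seed), length(seed) == 1)
  structure(
    list(dims = as.integer(dims), vox_mm = vox_mm, compartments = compartments,
         tissue_intensity = tissue_intensity, noise_sigma = noise_sigma,
         n_pairs = as.integer(n_pairs), ds_fraction = ds_fraction,
         seed = as.integer(seed)),
    class = "misl_phantom_spec"
  )
}

#' Build the phantom volumes from a spec
#'
#' Renders the compartment geometry deterministically (no randomness here):
#' an integer compartment-label volume, the ground-truth TCF volume, the
#' noise-free control-intensity volume, the per-voxel direct-saturation
#' volume, and the ground-truth mask set (brain, CSF, PVS) plus ROI names.
#' Compartments are painted in declaration order; later compartments
#' override earlier ones and overlaps are reported in `overlap_voxels`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `misl_phantom`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "misl_phantom_spec"))
  dims <- spec$dims
  coords <- voxel_coords(dims)
  brain <- ellipsoid_mask(dims, c(dims[1] / 2, dims[2] / 2, dims[3] / 2),
                          c(dims[1] * 0.44, dims[2] * 0.47, dims[3] * 0.44), coords)

  labels <- array(0L, dims)
  tcf <- array(0, dims)
  control <- array(0, dims)
  control[brain] <- spec$tissue_intensity
  ds <- array(0, dims)
  csf <- array(FALSE, dims)
  pvs <- array(FALSE, dims)
  overlap <- integer(0)
  roi_names <- character(0)

  for (i in seq_along(spec$compartments)) {
    cp <- spec$compartments[[i]]
    m <- switch(cp$geometry,
      ellipsoid = ellipsoid_mask(dims, cp$center, cp$radii, coords),
      shell = shell_mask(dims, cp$center, cp$radii, cp$thickness, coords),
      tube = tube_mask(dims, cp$from, cp$to, cp$radius, coords)
    )
    if (!any(m)) abort(sprintf("Compartment '%s' has no voxels on this grid.", cp$name))
    if (any(m & !brain)) {
      abort(sprintf("Compartment '%s' extends outside the brain envelope.", cp$name))
    }
    ov <- sum(m & labels > 0)
    overlap <- c(overlap, setNames(ov, cp$name))
    labels[m] <- i
    tcf[m] <- cp$tcf
    control[m] <- cp$intensity
    ds[m] <- if (is.na(cp$ds_fraction)) {
      if (cp$is_csf) spec$ds_fraction else 0
    } else cp$ds_fraction
    csf[m] <- cp$is_csf
    pvs[m] <- grepl("^pvs", cp$name)
    roi_names[as.character(i)] <- cp$name
  }
  # overrides may have carved earlier compartments; recompute CSF/PVS from labels
  for (i in seq_along(spec$compartments)) {
    cp <- spec$compartments[[i]]
    sel <- labels == i
    csf[sel] <- cp$is_csf
    pvs[sel] <- grepl("^pvs", cp$name)
  }
  if (any(overlap > 0)) {
    rlang::inform(sprintf("Overlapping compartments resolved by declaration order: %s.",
                          paste(sprintf("%s (%d voxels)", names(overlap)[overlap > 0],
                                        overlap[overlap > 0]), collapse = ", ")))
  }
  structure(
    list(labels = labels, tcf_truth = tcf, control_truth = control,
         ds_truth = ds, t2w = control,
         masks = list(brain = brain, csf = csf, pvs = pvs),
         roi_names = roi_names, overlap_voxels = overlap, spec = spec),
    class = "misl_phantom"
  )
}

#' @export
print.misl_phantom <- function(x, ...) {
  cat(sprintf("MISL digital phantom, %s grid, %d compartments:\n",
              paste(dim(x$labels), collapse = "x"), length(x$roi_names)))
  for (id in names(x$roi_names)) {
    sel <- x$labels == as.integer(id)
    cat(sprintf("  %-24s %5d voxels, TCF %6.1f\n", x$roi_names[[id]],
                sum(sel), max(x$tcf_truth[sel])))
  }
  invisible(x)
}

#' Simulate a noisy MISL acquisition of a phantom
#'
#' Forward-renders repeated control/label volumes. Control voxels carry the
#' compartment intensity; label voxels are reduced by the forward-model
#' delta-Z for the voxel's ground-truth TCF plus the compartment's
#' direct-saturation floor:
#' `label = control * (1 - misl_forward(params, tcf, t_sat) - ds)`.
#' Independent Rician noise (Gaussian sigma on each complex channel, then
#' magnitude) is added per volume; all randomness derives from the spec
#' seed, so identical spec + seed is bit-identical.
#'
#' @param phantom A [build_phantom()] result.
#' @param params A [misl_params()].
#' @param t_sat_s Saturation time in seconds (default: the standard 3.725 s).
#' @param n_pairs,noise_sigma,seed Override the spec values.
#' @return A [volume_series()] with attribute `t_sat_s`.
#' @export
simulate_acquisition <- function(phantom, params = misl_params(), t_sat_s = 3.725,
                                 n_pairs = NULL, noise_sigma = NULL, seed = NULL) {
  stopifnot(inherits(phantom, "misl_phantom"), inherits(params, "misl_params"))
  spec <- phantom$spec
  n_pairs <- n_pairs %||% spec$n_pairs
  noise_sigma <- noise_sigma %||% spec$noise_sigma
  seed <- seed %||% spec$seed

  dz <- misl_forward(params, as.numeric(phantom$tcf_truth), t_sat_s)
  total <- dz + as.numeric(phantom$ds_truth)
  if (any(total >= 1)) {
    abort("Unphysical phantom: delta-Z plus direct saturation reaches 1 in some compartment.")
  }
  control_truth <- as.numeric(phantom$control_truth)
  label_truth <- control_truth * (1 - total)

  dims <- dim(phantom$labels)
  nv <- prod(dims)
  add_rician <- function(s) {
    if (noise_sigma == 0) return(s)
    sqrt((s + rnorm(nv, 0, noise_sigma))^2 + rnorm(nv, 0, noise_sigma)^2)
  }
  control <- array(0, c(dims, n_pairs))
  label <- array(0, c(dims, n_pairs))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (i in seq_len(n_pairs)) {
    control[, , , i] <- add_rician(control_truth)
    label[, , , i] <- add_rician(label_truth)
  }
  out <- volume_series(control, label)
  attr(out, "t_sat_s") <- t_sat_s
  out
}
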