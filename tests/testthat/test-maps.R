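test_that("delta-S is the mean-control minus mean-label difference", {
  dims <- c(8, 8, 6)
  ctrl <- array(100, c(dims, 3)); lbl <- array(97, c(dims, 3))
  ds <- compute_delta_s(volume_series(ctrl, lbl))
  expect_true(all(ds$delta_s == 3))
  ds0 <- compute_delta_s(volume_series(ctrl, ctrl))
  expect_true(all(ds0$delta_s == 0))
  expect_error(volume_series(ctrl, array(97, c(9, 8, 6, 3))), "mismatch")
  expect_error(volume_series(ctrl, array(97, c(dims, 2))), "repeat counts")
})

test_that("delta-Z divides only inside the mask above the low-signal guard", {
  dims <- c(6, 6, 4)
  mean_control <- array(100, dims)
  mean_control[1, 1, 1] <- 1            # below guard
  delta_s <- array(3, dims)
  mask <- array(TRUE, dims); mask[6, 6, 4] <- FALSE
  out <- compute_delta_z(delta_s, mean_control, mask, low_signal_guard = 10)
  expect_equal(out$delta_z[2, 2, 2], 0.03)
  expect_true(is.na(out$delta_z[1, 1, 1]))   # guarded, not zero-filled
  expect_true(is.na(out$delta_z[6, 6, 4]))   # outside mask
  expect_equal(out$qc$n_low_signal, 1)
  expect_equal(out$qc$n_defined, prod(dims) - 2)
})

test_that("TCF map is the elementwise inversion with NA propagation and linearity", {
  p <- protocol_params()
  dz <- array(c(0.0447, NA, 0), c(3, 1, 1))
  tcf <- compute_tcf_map(dz, p, protocol_t_sat)
  expect_equal(tcf[1, 1, 1], 288, tolerance = 5e-3)
  expect_true(is.na(tcf[2, 1, 1]))
  expect_equal(tcf[3, 1, 1], 0)
  expect_equal(compute_tcf_map(dz * 2, p, protocol_t_sat)[1, 1, 1],
               2 * tcf[1, 1, 1], tolerance = 1e-12)
})

test_that("CSF mask isolates the bright compartment, absolute and Otsu rules agree", {
  b <- bimodal_volume()
  m_abs <- make_csf_mask(b$volume, b$brain_mask, threshold = 500)
  expect_identical(which(m_abs), which(b$csf_mask))
  m_otsu <- make_csf_mask(b$volume, b$brain_mask, threshold = "otsu")
  expect_identical(which(m_otsu), which(b$csf_mask))
  expect_true(attr(m_otsu, "threshold") > 50 && attr(m_otsu, "threshold") < 1000)
  expect_error(make_csf_mask(array(50, c(4, 4, 4)), array(TRUE, c(4, 4, 4)),
                             threshold = 500), "empty")
})

test_that("PVS masking keeps small components and drops large CSF structures", {
  dims <- c(32, 32, 24)
  vol <- array(0, dims)
  brain <- array(TRUE, dims)
  # a large ventricle-like block and three small tubes
  vol[4:20, 4:20, 4:20] <- 1000          # 17^3 = 4913 voxels
  vol[26, 26, 2:8] <- 1000
  vol[28, 28, 2:8] <- 1000
  vol[30, 5, 10:16] <- 1000
  pvs <- make_pvs_mask(vol, brain, intensity_threshold = 500,
                       max_component_size = 300)
  expect_equal(sum(pvs), 21)
  expect_false(any(pvs[4:20, 4:20, 4:20]))
  expect_warning(empty <- make_pvs_mask(array(0, dims), brain, 500),
                 "No suprathreshold")
  expect_equal(sum(empty), 0)
})

test_that("connected-component connectivity changes diagonal-touching structures", {
  dims <- c(10, 10, 4)
  mask <- array(FALSE, dims)
  mask[2:4, 2, 2] <- TRUE
  mask[5:7, 3, 2] <- TRUE   # touches the first tube only diagonally
  lab26 <- label_components(mask, connectivity = 26)
  lab6 <- label_components(mask, connectivity = 6)
  expect_equal(max(lab26), 1)
  expect_equal(max(lab6), 2)
})

test_that("ROI dilation assigns CSF voxels to the nearest label with deterministic ties", {
  dims <- c(9, 5, 3)
  rois <- array(0L, dims)
  rois[2, 3, 2] <- 1L
  rois[6, 3, 2] <- 2L
  csf <- array(TRUE, dims)
  # radius 0: plain intersection
  r0 <- dilate_and_intersect_rois(rois, csf, dilation_radius = 0)
  expect_identical(which(r0 > 0), which(rois > 0))
  # radius 1: gains face neighbors
  r1 <- dilate_and_intersect_rois(rois, csf, dilation_radius = 1)
  expect_equal(r1[3, 3, 2], 1L)
  expect_equal(r1[5, 3, 2], 2L)
  # equidistant voxel between labels 1 and 2 goes to the lower id
  r2 <- dilate_and_intersect_rois(rois, csf, dilation_radius = 2)
  expect_equal(r2[4, 3, 2], 1L)
  # intersection with CSF is respected
  csf2 <- array(FALSE, dims); csf2[3, 3, 2] <- TRUE
  r3 <- dilate_and_intersect_rois(rois, csf2, dilation_radius = 1)
  expect_equal(sum(r3 > 0), 1)
  expect_equal(r3[3, 3, 2], 1L)
})

test_that("ROI statistics aggregate correctly, composites are voxel-weighted", {
  dims <- c(6, 6, 2)
  rois <- array(0L, dims)
  rois[1:2, 1:3, 1] <- 1L   # 6 voxels
  rois[4:6, 1:2, 1] <- 2L   # 6 voxels
  dz <- array(NA_real_, dims)
  dz[rois == 1] <- 0.03
  dz[rois == 2] <- 0.06
  tcf <- dz * 100
  tab <- roi_statistics(dz, tcf, rois, roi_names = c("1" = "a", "2" = "b"),
                        composites = list(both = c(1, 2)))
  a <- tab[tab$roi_name == "a", ]
  expect_equal(a$mean_dz, 0.03)
  expect_equal(a$sd_dz, 0)
  expect_equal(a$n_voxels, 6)
  both <- tab[tab$roi_name == "both", ]
  expect_equal(both$mean_dz, 0.045)  # equal-count-weighted mean of parts
  expect_equal(both$n_voxels, 12)
  # an ROI with no defined voxels is missing, not zero
  dz[rois == 2] <- NA
  tab2 <- roi_statistics(dz, tcf, rois)
  b2 <- tab2[tab2$roi_name == "2", ]
  expect_equal(b2$n_voxels, 0)
  expect_true(is.na(b2$mean_dz))
})

test_that("aggregation is invariant to repeat ordering and masks never alter intensities", {
  ph <- quiet_phantom(noise_sigma = 10, n_pairs = 4, seed = 5)
  ser <- simulate_acquisition(ph)
  perm <- c(3, 1, 4, 2)
  ser2 <- volume_series(ser$control[, , , perm], ser$label[, , , rev(perm)])
  p <- protocol_params()
  q1 <- misl_quantify(ser, p, protocol_t_sat, csf_mask = ph$masks$csf,
                      pvs_mask = ph$masks$pvs, brain_mask = ph$masks$brain,
                      roi_labels = ph$labels, roi_names = ph$roi_names)
  q2 <- misl_quantify(ser2, p, protocol_t_sat, csf_mask = ph$masks$csf,
                      pvs_mask = ph$masks$pvs, brain_mask = ph$masks$brain,
                      roi_labels = ph$labels, roi_names = ph$roi_names)
  expect_equal(q1$region_table, q2$region_table)
  # delta-S is computed on all voxels regardless of masks
  ds_ref <- compute_delta_s(ser)$delta_s
  expect_equal(q1$delta_s, ds_ref)
})
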