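# misl

Quantification of tissue–CSF water exchange from **magnetization transfer
indirect spin labeling (MISL)** MRI.

MISL labels brain-parenchyma water with a train of off-resonance MT pulses
and detects its exchange into cerebrospinal fluid as a small drop of the CSF
signal on a long-TE (CSF-only) readout. The normalized control-minus-label
difference,

    ΔZ = (S_control − S_label) / S_control,

is converted into a **tissue-to-CSF flow** (TCF, mL of tissue water per
100 mL of CSF per minute) by inverting the compartmental model

    ΔZ = α · (TCF/6000) · (1/R1,CSF) · [ 1 + e^(−R1ρ·t_sat) · R1,CSF/R1,app
                                           − e^(−R1,CSF·t_sat) · R1ρ/R1,app ],

with `R1,app = R1ρ,tissue − R1,CSF`, labeling efficiency `α` measured per
subject as the tissue MT plateau, and defaults `α = 0.42`,
`R1ρ,tissue = 1.72 s⁻¹`, `R1,CSF = 0.23 s⁻¹`, `t_sat = 3.725 s`.

This package is aimed at quantitative-MRI researchers who want to analyse
MISL acquisitions or study the method itself. It provides:

* the closed-form signal model and its exact inverse, with the
  `R1,app → 0` removable singularity handled by a series expansion
  (`misl_forward()`, `tcf_from_delta_z()`, `delta_z_tissue()`,
  `fit_saturation_curve()`);
* a single-pool Bloch simulator of the shaped labeling train that bounds
  CSF direct saturation (`simulate_saturation()`, `z_spectrum()`,
  `make_pulse()`, `cw_equivalent_b1()`);
* the voxelwise mapping pipeline from repeated control/label NIfTI volumes
  to ΔS/ΔZ/TCF maps with CSF masking, perivascular-space (PVS)
  segmentation and ROI aggregation (`misl_quantify()`, `make_csf_mask()`,
  `make_pvs_mask()`, `roi_statistics()`);
* a digital head phantom with known compartmental flow and Rician noise
  for end-to-end validation (`phantom_spec()`, `build_phantom()`,
  `simulate_acquisition()`);
* test–retest and age-trend statistics (`icc_two_session()`,
  `bland_altman()`, `age_regression()`) plus ggplot2 figures
  (`autoplot()`, `plot_z_spectrum()`, `plot_bland_altman()`,
  `plot_age_trend()`, `plot_map_slice()`);
* a command-line interface: `misl simulate-ds | fit-r1rho | make-phantom |
  quantify | report` (installed at `exec/misl`).

See the methods vignette (`vignettes/misl-methods.Rmd`) for the model,
numerical choices, and what the phantom does and does not emulate.

## Worked example

Fit the tissue saturation-buildup curve, invert group-mean ΔZ values, bound
direct saturation, and run the full pipeline on a noisy phantom:

```r
library(misl)

params <- misl_params()
#> MISL model parameters: alpha = 0.42, R1rho(tissue) = 1.72 1/s, R1(CSF) = 0.23 1/s (R1app = 1.49 1/s)

# saturation buildup measured at the five protocol train lengths
tt <- c(0.5, 1.025, 2, 2.975, 3.725)
curve <- tibble::tibble(t_sat_s = tt, delta_z = 0.42 * (1 - exp(-1.72 * tt)))
fit_saturation_curve(curve)
#> Saturation-buildup fit: alpha = 0.42, R1rho(tissue) = 1.72 1/s (residual norm 5.55e-17, n = 5)

# group-mean delta-Z -> TCF (mL/100 mL/min)
round(tcf_from_delta_z(params, c(cp = 0.0447, pvs = 0.0836), t_sat_s = 3.725), 1)
#>    cp   pvs
#> 287.9 538.4

# CSF direct saturation of the full 50-pulse train at the -10 ppm offset
ds <- simulate_saturation(spin_pool(4350, 2000), saturation_scheme())$ds
sprintf("DS at -10 ppm: %.3f%%", 100 * ds)
#> "DS at -10 ppm: 0.258%"

# phantom with known flow, 18 noisy control/label pairs at CSF SNR 50
ph   <- build_phantom(phantom_spec(seed = 7, ds_fraction = 0))
ser  <- simulate_acquisition(ph)
maps <- misl_quantify(ser, params, t_sat_s = 3.725,
                      brain_mask = ph$masks$brain, pvs_mask = ph$masks$pvs,
                      roi_labels = ph$labels, roi_names = ph$roi_names)
maps
#> MISL maps on a 64x64x48 grid: 20073 defined voxels (0 low-signal excluded, 202 negative delta-Z)
#> Region table: 10 rows
dplyr::select(maps$region_table, roi_name, n_voxels, mean_dz, mean_tcf)
#>                   roi_name n_voxels   mean_dz mean_tcf
#> 1                      sas    18022  0.023271   149.87
#> 2   lateral_ventricle_left      670  0.015618   100.58
#> 3  lateral_ventricle_right      670  0.015686   101.02
#> 4      choroid_plexus_left       51  0.045231   291.30
#> 5     choroid_plexus_right       51  0.045513   293.12
#> 6                    pvs_1       67  0.083713   539.13
#> 7                    pvs_2       67  0.083906   540.38
#> 8                    pvs_3       81  0.084326   543.09
#> 9                    pvs_4       47  0.082890   533.83
#> 10                    cyst      347 -0.000727    -4.68
```

The recovered per-compartment TCF matches the generating values (ventricles
100, subarachnoid shell 150, choroid plexus 288, PVS tubes 543) to within
about 2% at this noise level, and the zero-flow cyst mean ΔZ is consistent
with zero — the same chain of checks the test suite runs.

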