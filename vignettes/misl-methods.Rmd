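---
title: "Quantifying tissue-CSF water exchange with MISL: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue-CSF water exchange with MISL: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misl)
```

## The measurement

Magnetization transfer indirect spin labeling (MISL) measures how fast water
moves from brain tissue into the cerebrospinal fluid (CSF). A train of
off-resonance RF pulses saturates ("labels") the water magnetization of the
parenchyma through magnetization transfer, while leaving CSF essentially
untouched because CSF contains almost no semi-solid macromolecules. Labeled
tissue water then exchanges into the CSF — across the ependyma, the pia, and
most visibly within perivascular spaces (PVS) — where it slightly lowers the
CSF signal. A long-TE readout (effective TE on the order of a second)
suppresses everything except long-T2 fluid, so the images are essentially
pure CSF. Subtracting the labeled acquisition from an unlabeled control
acquisition isolates the exchanged water.

Three maps are derived:

* **ΔS** `= mean(control) − mean(label)` — the raw difference image;
* **ΔZ** `= ΔS / mean(control)` — the normalized exchange fraction;
* **TCF** — the tissue-to-CSF flow in mL of tissue water per 100 mL of CSF
  per minute, obtained by inverting the compartmental signal model below.

## Signal model

Tissue saturation builds up mono-exponentially during the train:

$$\Delta Z_\mathrm{tissue}(t) \;=\; \alpha\,\bigl(1 - e^{-R_{1\rho}t}\bigr),$$

where $\alpha$ is the labeling efficiency (the steady-state tissue MT
fraction) and $R_{1\rho}$ the rotating-frame longitudinal relaxation rate of
tissue water during the train. `fit_saturation_curve()` estimates both from
a variable-duration acquisition; with the standard protocol the durations
are 0.5, 1.025, 2, 2.975 and 3.725 s, and representative human values are
$\alpha = 0.42$ and $R_{1\rho} = 1.72\,\mathrm{s^{-1}}$. Because the buildup
at the full 3.725 s train is already at its plateau
($\Delta Z_\mathrm{tissue}(3.725\,\mathrm{s}) \approx \alpha$), $\alpha$ can
be measured per subject from a single full-length acquisition.

The CSF signal drop produced by a flow TCF after saturation time $t$ is

$$\Delta Z \;=\; \alpha\,\frac{\mathrm{TCF}}{6000}\,\frac{1}{R_{1,\mathrm{CSF}}}
\left[1 + e^{-R_{1\rho}t}\,\frac{R_{1,\mathrm{CSF}}}{R_{1,\mathrm{app}}}
        - e^{-R_{1,\mathrm{CSF}}t}\,\frac{R_{1\rho}}{R_{1,\mathrm{app}}}\right],$$

with $R_{1,\mathrm{app}} = R_{1\rho} - R_{1,\mathrm{CSF}}$ and the constant
6000 converting mL/100 mL/min into fractional CSF volume turnover per
second. The model is linear in TCF, so `tcf_from_delta_z()` is its exact
algebraic inverse. Two numerical points deserve mention:

* **Removable singularity.** The bracket is continuous as
  $R_{1,\mathrm{app}} \to 0$ but numerically unstable there; below
  $|R_{1,\mathrm{app}}| < 10^{-4}\,\mathrm{s^{-1}}$ the package switches to
  the second-order series
  $1 - e^{-rt}(1+rt) + e^{-rt}r\left(R_{1,\mathrm{app}}t^2/2 -
  R_{1,\mathrm{app}}^2 t^3/6\right)$ (with $r = R_{1,\mathrm{CSF}}$), which
  agrees with a two-sided numeric limit to better than $10^{-8}$ relative.
* **Buildup form.** Some statements of the buildup equation carry the same
  TCF/6000 factor as the CSF equation; that factor is inconsistent with
  $\alpha$ being the steady-state tissue MT fraction and with the measured
  plateau $\Delta Z_\mathrm{tissue}(3.725\,\mathrm{s}) = 0.42 \approx
  \alpha$. The package therefore implements the buildup without it.

Defaults are $\alpha = 0.42$, $R_{1\rho} = 1.72\,\mathrm{s^{-1}}$ and the
literature CSF relaxation rate $R_{1,\mathrm{CSF}} = 0.23\,\mathrm{s^{-1}}$
(CSF $T_1 \approx 4350$ ms); all are plain arguments of `misl_params()`.
Negative ΔZ voxels (noise) invert to negative TCF and are kept and counted,
never clamped: clamping would bias ROI means upward.

```{r}
params <- misl_params()
tcf_from_delta_z(params, c(0.0447, 0.0836), t_sat_s = 3.725)
```

## Bloch simulation of direct saturation

The main confound of MISL is direct saturation (DS): the labeling RF
slightly saturating CSF water itself. The package bounds DS with a
single-pool Bloch simulation of the full train (`simulate_saturation()`,
`z_spectrum()`): hard-pulse discretization of the shaped pulses at a 50 us
default step, each step solved *exactly* as the matrix exponential of the
constant-coefficient Bloch system (eigendecomposition with a
scaling-and-squaring fallback), closed-form relaxation during the
interpulse delays, and transverse spoiling at the end of each delay
(gradient-spoiler assumption; the DS bound changes negligibly with spoiling
off, because the zero-edged pulse returns magnetization adiabatically).

The protocol pulse is a "SincGaussian": here, a single-main-lobe sinc
(time-bandwidth product 2, so the envelope is exactly zero at the pulse
edges) apodized by a Gaussian window. The Gaussian width is the one free
constant and is fixed once by `calibrate_sincgauss()` so that the 3 uT-peak
pulse has the protocol's stated 1.90 uT continuous-wave-equivalent
amplitude, read as RMS over the pulse (the vendor convention). The
alternative reading — RMS over the pulse-plus-delay period — cannot be
reconciled with a zero-edged envelope at the 50/25 ms duty cycle, and
envelopes fat enough to reach it acquire edge discontinuities that triple
the simulated DS; `cw_equivalent_b1()` exposes both conventions.

With CSF at $T_1/T_2 = 4350/2000$ ms, the simulated DS of the full 50-pulse
train at the −10 ppm labeling offset is 0.258% — matching the 0.26%
simulation bound and the 0.30% measured in an exchange-free arachnoid cyst
— and is three orders of magnitude smaller at the 200 ppm control offset,
which justifies treating the control as unsaturated. Varying the two shape
constants by ±20% keeps DS in the 0.22–0.34% range: the bound is not an
artifact of the exact envelope choice, though time-bandwidth products below
2 (non-zero edges) do push DS slightly above the calibrated value.

## Mapping pipeline

`misl_quantify()` chains the voxelwise stages downstream of registration
(inputs are pre-aligned by contract; any grid mismatch is an error, never a
silent resample):

1. **Averaging and ΔS** over the repeated control/label pairs (18 by
   default).
2. **CSF mask**: the long-TE control image is bimodal (bright CSF against
   2%-level suppressed tissue), so Otsu's rule on the brain-masked
   histogram is a reproducible default; an absolute cutoff can be supplied
   instead.
3. **ΔZ** only inside CSF ∪ PVS and only where the control signal clears a
   low-signal guard (default 5× the background MAD): outside CSF the
   denominator is residual noise and ΔZ is meaningless. Undefined voxels
   are `NA`, never zero.
4. **TCF** by exact elementwise inversion, `NA` propagating.
5. **PVS mask** from a high-resolution long-TE T2w volume: threshold,
   3D connected components (26-connectivity default), drop components
   larger than 300 voxels (ventricles, subarachnoid sheets), keep the
   small tubes.
6. **ROI aggregation**: atlas labels are dilated by a voxel ball (radius 1
   default) and intersected with the CSF mask — contested voxels go to the
   nearest label, exact ties to the lower id, deterministically — then
   per-ROI and composite means/SDs are tabulated, excluding undefined
   voxels. Empty ROIs are reported as missing, not zero.

Masks only gate where values are defined and aggregated; stored intensities
are never modified.

## The digital phantom

Because no public in-vivo MISL data exist, validation uses a synthetic head
phantom (`phantom_spec()`, `build_phantom()`, `simulate_acquisition()`)
whose compartments have *known* flow: two lateral-ventricle ellipsoids
(TCF 100), a subarachnoid shell (150), choroid-plexus blobs inside the
ventricles (288), four perivascular tubes of 1.4-voxel radius in deep
tissue (543), and a zero-flow cyst that mirrors the arachnoid-cyst DS
control. The default grid is 64×64×48 at a nominal 2 mm; compartment TCF
values mirror the human group means so the rendered ΔZ sits in the
realistic 2–9% range.

The acquisition model renders, per repeat, `control = compartment
intensity` (CSF 1000, tissue 20 — the 2% long-TE residual) and
`label = control × (1 − ΔZ(TCF) − DS)`, then adds Rician noise (Gaussian
sigma per complex channel, default 20, i.e. CSF SNR 50 — a realistic
18-average long-TE regime). The DS floor defaults to 0.003, the measured
cyst value, so DS-induced bias is itself testable; the floor is set to zero
for the exact round-trip and zero-mean cyst tests, which probe the
exchange-free, DS-free ideal. All randomness derives from an explicit seed.

What the phantom does *not* emulate: partial-volume mixing at compartment
boundaries, motion, B0/B1 inhomogeneity, k-space/TSE readout effects, or
anatomical realism beyond compartment topology. Passing the phantom tests
therefore demonstrates correctness of the quantification chain, not
robustness to acquisition artifacts.

Problem sizes were chosen so the full validation suite (phantom at
64×64×48 with 18 pairs, 200-replicate Monte Carlo fit, full 50-pulse Bloch
simulations) runs in well under a minute.

## Group statistics

`age_regression()` fits ordinary least squares of a regional metric on age
per region, with a two-sided t-test on the slope and no multiple-testing
correction across regions (raw p-values, as is conventional for this
seven-composite design). `icc_two_session()` implements the single-measure
two-way random-effects absolute-agreement ICC(2,1) — the standard
test-retest choice for a design that pools subject-by-ROI pairs across
sessions — from the two-way ANOVA mean squares, with the F-based 95%
confidence interval; ICC(3,1) (consistency) is available via `type =
"consistency"`. The published reliability notation is ambiguous between
the two; ICC(2,1) is implemented as the primary and the choice is an
engineering decision, not a claim about the original analysis.
`bland_altman()` reports the mean session difference and
`bias ± 1.96 × SD` limits of agreement. In-vivo reliability and age-slope
values depend on human data that is not redistributable; the package
validates these routines against closed-form oracles on synthetic tables
instead.

## Known limitations

* Single-pool DS simulation only: the tissue MT Z-spectrum would need a
  two-pool Bloch-McConnell model whose bound-pool parameters are not
  specified by the protocol.
* The quantification assumes global $\alpha$, $R_{1\rho}$,
  $R_{1,\mathrm{CSF}}$; regional or age-related variation in these
  constants propagates directly into TCF.
* No registration or motion correction is included — inputs must be
  pre-aligned, and the pipeline refuses rather than resamples.
* The empirical CSF intensity cutoff and the 300-voxel PVS component
  cutoff are engineering defaults, exposed as arguments.
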