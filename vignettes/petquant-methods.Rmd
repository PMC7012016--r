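---
title: "petquant: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petquant: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the numerical choices, what the
synthetic world does and does not emulate, and the places where the design
was genuinely open and a choice had to be made.

## The problem

Reference-tissue quantification of brain PET replaces arterial blood
sampling with a time-activity curve (TAC) from a region devoid of specific
binding — cerebellar gray matter for most tracers, occipital cortex for
μ-opioid ligands whose cerebellum is not binding-free. Manual delineation
of that region is operator-dependent; the package automates it and
provides the statistics used to measure what operator dependence costs.

## Automatic reference-region generation

Three stages, each materialized so a failed run can be audited:

1. **Label extraction.** The union of configured label codes from an
   integer parcellation on the PET grid (FreeSurfer color-table convention
   by default: cerebellar cortex 8/47, lateral ventricles 4/43, occipital
   aparc parcels 1005/1011/1013/1021 plus right-hemisphere counterparts).
   The code list ships in the config rather than being hard-coded because
   the exact occipital composition is a site decision. Label volumes on a
   different grid are rejected, not resampled: resampling belongs to the
   upstream registration pipeline, which is out of scope.
2. **Anatomical correction.** For the cerebellar reference, a morphological
   erosion with a 6-connected structuring element, default depth 1 voxel —
   the minimal faithful reading of "peel the outermost voxels", where
   spill-in from occipital cortex and venous sinuses concentrates. Whether
   the peel should be metric (mm) or voxel-based is not determinable from
   published descriptions; voxel-based is chosen for grid independence and
   the depth is configurable. For the occipital reference, voxels whose
   world |x| strictly exceeds the per-hemisphere maximum |x| of the
   lateral-ventricle voxels are removed ("lateral" = the world left-right
   axis of the RAS affine; the neuroimaging default in the absence of a
   stated convention). If one hemisphere has no ventricle voxels the
   global maximum is used, with a warning.
3. **Tail exclusion.** A functionally homogeneous region should show an
   approximately Gaussian radioactivity distribution; voxels in the tails
   (CSF partial volume, spill-in from hot neighbors) are excluded. The
   distribution of in-mask intensities of the *duration-weighted* mean PET
   image is estimated by a Gaussian kernel density (Silverman bandwidth,
   512 grid points spanning the sample range); bounds are placed where the
   density first falls to half its modal value on each side, located by
   linear interpolation; voxels inside the closed interval are kept. If
   the density never crosses half-max on a side (e.g. a shoulder from a
   bimodal contamination), the sample extreme is used on that side, with a
   warning. Duration weighting of the mean image matters because an
   unweighted mean over frames of very different lengths over-represents
   the short early frames. Whether the original bounds were computed on a
   histogram or a smoothed density is unstated in the literature this
   design follows; KDE avoids bin-width sensitivity, and the settings are
   recorded in the run report. Masks under 100 voxels skip the step (a
   KDE on fewer points is unstable) with a warning.

Note a consequence of the FWHM definition: for *purely Gaussian* in-mask
noise the interval μ ± 1.1774σ retains ≈76% of voxels by construction.
The step is a tail-trimmer, not a no-op, even on clean data; on a
noiseless phantom the distribution is degenerate and nothing is excluded.
Tail exclusion is deliberately not idempotent — re-applying it to an
already-trimmed mask re-estimates the density and may shrink further.

## Kinetic models and numerics

All models share one numerical backbone. Input curves are interpolated
linearly onto a uniform fine grid (step 0.25 s expressed in minutes),
anchored at (0, 0) when the first sample is after injection. Convolution
with `exp(−θt)` uses the exact solution for a piecewise-linear input,
evaluated as a linear recurrence (`stats::filter`), so convolution error
is limited by the interpolation, not the quadrature.

**Frame averaging.** The scanner integrates activity over each frame
interval; the phantom generator therefore emits frame-interval *averages*,
not midpoint samples. The nonlinear and basis-function fits evaluate their
models the same way. An earlier design evaluated fitted models at frame
midpoints and accepted the average-vs-midpoint mismatch as realism; on the
default schedule that mismatch left a 0.7% bias in SRTM R1 and >1% in
2TCM k3 — larger than the 0.5% round-trip tolerance the package holds
itself to — so the design was changed: the fit now applies the same
interval integration as the acquisition. The instantaneous R1 term of the
SRTM uses the measured reference frame values directly (they already *are*
frame averages of the reference concentration); only the convolution term
needs the interpolated fine-grid curve. The graphical (Logan/Patlak)
models operate on frame-midpoint samples, as those plots are defined.

**SRTM (regional).** `C_T = R1·C_R + (k2 − R1·k2a)·C_R ⊗ e^{−k2a t}` with
`k2a = k2/(1+BP_ND)`. For fixed k2a the model is linear in (R1, φ), so
the fit profiles the 1-D k2a problem: the weighted linear subproblem is
solved exactly on a 64-point log-spaced k2a grid over [0.006, 0.6] /min,
and the best bracket is refined by Brent search. This variable-projection
scheme replaced a 5-start bounded NLS: it is deterministic, ~10× faster,
and — decisive for correctness — handles the flat ridge at BP_ND ≈ 0,
where k2 is weakly identified and the multistart optimizer would stall at
BP_ND ~ 10⁻³ on data where the exact answer is 0. Estimates outside
R1 ∈ (0, ∞), k2 > 0, BP_ND ∈ (−0.9, 30] raise an error rather than being
silently clipped.

**SRTM (voxelwise).** The basis-function method: the same linearization,
with a fixed 64-point log-spaced k2a grid shared by all voxels, each voxel
solved by 2-parameter least squares per basis and assigned the
rss-minimizing basis. Failed voxels (nonfinite or R1 ≤ 0) become NaN and
are counted.

**Logan / Patlak.** Ordinary least squares on the standard transformed
coordinates for frames with `t_mid ≥ t*`; t* is configuration-fixed per
tracer (automatic t* selection would be invented behavior). The
reference-input Logan `C_R(T)/k2'` term is optional and off by default —
whether the original pipeline includes it is unstated, so both variants
are exposed. Plasma-input variants require the plasma record to cover the
fitted frames; silent extrapolation was an early bug class and is now an
error.

**2TCM (regional only).** Analytic biexponential impulse response
convolved with plasma; seeded multistart (10 draws) of a box-bounded
quasi-Newton fit, followed by one tight polish (relative tolerance 1e−15)
from the best basin. The 2TCM objective is flat enough that a single-stage
fit at practical tolerances leaves >1% parameter error on noiseless data.
The model's convolution grid is 0.5 s: the induced parameter error
(~0.01% on the default schedule) is far below fit tolerances at half the
cost. `V_T = (K1/k2)(1 + k3/k4)` is reported when k4 > 0; k4 pinned at
its zero bound sets an `irreversible` flag instead.

**Weights.** Uniform by default (the weighting used by the original
pipeline is unstated); duration and duration-over-activity schemes are
available, normalized to sum to the frame count.

## The synthetic world

The phantom emulates what the estimators consume, not scanner physics.

- **Input function:** the classic triexponential bolus parameterisation
  (A1 = 851.1 kBq/ml/min, A2 = 21.9, A3 = 20.8 kBq/ml,
  λ = −4.1339, −0.1191, −0.0104 /min, delay 0.7 min) — the field-standard
  realistic instantiation of this functional form.
- **Geometry:** a 40×40×40 grid of 2 mm voxels, origin at the grid center
  (RAS), holding a reference sphere (label 8), two target spheres (17,
  18) and two ventricle-proxy boxes (4, 43) for the lateral-cut path.
  Small enough that the full suite runs in CI time.
- **Schedule:** 97 min in 33 frames (4×15 s … 13×300 s). The early frames
  are short enough that frame averages and midpoint samples of the tissue
  curves agree to <0.5%, which is asserted as a test.
- **Noise:** Gaussian with per-voxel-frame sd `scale·sqrt(C/Δt)` — the
  standard pseudo-realistic dynamic-PET model in which variance scales
  with count rate and inversely with frame duration. Default scale 0.05
  gives ~5% noise on late 5-min frames. All randomness flows through one
  seeded generator; identical seeds give bit-identical phantoms.
- **Operator masks:** each simulated operator draws `slice_count`
  consecutive transaxial slices, jittered around the region's central
  slice, of the true region eroded/dilated by a per-operator margin —
  emulating the variance structure of a three-slice manual protocol
  (which slices, how generous the boundary), not its anatomy.

What a green test does **not** establish: behavior under scanner
resolution (no point-spread blurring, so spill-over exists here only when
a test paints it explicitly), attenuation/scatter/randoms, motion, decay
(inputs are assumed decay-corrected), or anatomical realism of the
regions. Claims about real-data bias are outside what this test bed can
support.

## Evaluation statistics

Spatial overlap is deliberately asymmetric — `100·|A∩M|/|M|` with the
manual mask as denominator — because the question asked is "how much of
the manual region does the automatic one cover". ICCs come from the
crossed random-effects model `value ~ 1 + (1|operator) + (1|study)`,
estimated by REML (`lme4`) rather than the Bayesian fit used in the
original analysis: deterministic, dependency-light, and asymptotically
equivalent for these designs. A component's ICC is its share of the total
variance (study + operator + residual), so both lie in [0, 1]; REML's
boundary estimates at 0 play the role of clipping. The single "ICC"
usually reported is interpreted as the study component (consistency of
studies across operators); both components are always returned so the
choice is visible. Reference-TAC AUCs are standardized by the per-study
mean activity in the union of all operators' masks before the ICC, which
removes scanner/dose/body-mass scale differences — a per-study scale
factor provably cancels, and a test asserts it. Degenerate designs with
literally zero variance (zero-jitter simulations) short-circuit to
icc_study = 1 / icc_operator = 0 rather than asking REML to partition
nothing. Distribution mode and FWHM bounds reuse the exact KDE settings
of the tail-exclusion step so that the two reports are comparable;
skewness is the adjusted Fisher–Pearson statistic.

## Degenerate inputs and tie-breaks

- Intensities exactly at a tail-exclusion bound are kept (closed
  interval): deterministic and inclusive.
- Constant-intensity masks produce degenerate bounds and no exclusion.
- NaN voxels are dropped per frame with a logged count; a frame losing
  all mask voxels is an error naming the frame.
- Affine agreement is checked to 1e−4 per element (catches resampling
  mistakes, tolerates float round-trips); shapes must match exactly.
- Time is minutes internally everywhere; files carry seconds and are
  converted at the I/O boundary.

## Known limitations

No partial-volume correction, no voxelwise 2TCM, no plasma metabolite
correction or extrapolation (assumed done upstream), no motion
correction/coregistration/normalization (delegated to external tools),
and the NIfTI layer implements the NIfTI-1 single-file subset the package
itself writes (sform affines; datatypes uint8/int16/int32/float32/
float64), which covers standard neuroimaging exports but not NIfTI-2 or
dual-file pairs.
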