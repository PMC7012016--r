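# petquant

Automated reference-region quantification for dynamic brain PET.

Quantifying receptor binding or tracer uptake from a dynamic brain PET scan
usually requires a *reference region* — tissue devoid of specific binding
that supplies the nondisplaceable input to the kinetic model. Drawing that
region by hand is the traditional gold standard, but it is slow and
operator-dependent: different trained operators produce visibly different
masks, different reference time-activity curves (TACs), and ultimately
different binding potentials. `petquant` implements the automated
alternative and the statistical machinery to evaluate it:

- **Automatic reference-region generation** from an anatomical parcellation
  (FreeSurfer-convention label codes): label extraction, an anatomical
  correction (surface erosion for the cerebellar reference; removal of
  voxels lateral to the lateral ventricles for the occipital reference),
  and exclusion of voxels in the tails of the radioactivity distribution
  using full-width-at-half-maximum (FWHM) bounds on a kernel density
  estimate.
- **Kinetic models**: the simplified reference tissue model
  (`C_T = R1 C_R + (k2 − R1 k2a) C_R ⊗ e^{−k2a t}`, `k2a = k2/(1+BP_ND)`),
  both regionally (variable-projection NLS) and voxelwise (basis-function
  method); Logan and Patlak graphical analyses with plasma or reference
  input (slopes DVR/V_T and K_i); SUV ratio over a time window; fractional
  uptake ratio (FUR); and the regional two-tissue compartment model.
- **Evaluation statistics** for operator variability: asymmetric spatial
  overlap (`100·|A∩M|/|M|`), crossed random-effects variance components
  (`y ~ 1 + (1|operator) + (1|study)`, REML) and the ICCs derived from
  them, AUC standardization, distribution descriptors (mean, SD, KDE mode,
  skewness) and distribution overlap, relative bias, Pearson correlation.
- **A seeded 4D phantom simulator** (triexponential bolus input, forward
  kinetic models with scanner-like frame averaging, frame-duration-scaled
  Gaussian noise, simulated multi-operator manual masks) providing ground
  truth for everything above.

Audience: PET methodologists and imaging statisticians who want a tested,
scriptable quantification core with known-truth validation, without manual
drawing steps.

## Worked example

```r
library(petquant)

# a 40x40x40, 2 mm phantom: cerebellum-proxy reference sphere (label 8,
# one-tissue kinetics), one SRTM target sphere (label 17, BP_ND = 1.5),
# 5% frame-duration-scaled noise
ph <- build_phantom(
  phantom_spec(noise = list(type = "gaussian", scale = 0.05), seed = 42),
  region_kinetics(8L, "1tcm", list(K1 = 0.1, k2 = 0.1)),
  list(region_kinetics(17L, "srtm", list(R1 = 1.2, k2 = 0.15, BP_ND = 1.5))))

cfg <- default_tracer_config("raclopride")   # SRTM, eroded cerebellar ref
res <- run_pipeline(ph$image, ph$labels, cfg, roi_codes = 17L,
                    out_dir = "out/")
res$refregion$volumes_ml
#>    raw   anat  final
#> 11.616  7.872  5.952
res$fits[["17"]]$params$BP_ND
#> [1] 1.500172
```

The reference region shrinks from 11.6 ml (raw cerebellar labels) to
7.9 ml after the 1-voxel surface erosion and 6.0 ml after FWHM tail
exclusion, and the SRTM binding potential of the target region is
recovered to 0.01% despite the noise. `out/` holds the three mask stages,
all TACs, and a JSON run report; reruns are bit-identical.

The same pipeline runs from the command line:

```sh
Rscript inst/cli/petquant simulate  --out sim/ --seed 5 --noise 0.05
Rscript inst/cli/petquant run --pet sim/phantom.nii.gz \
    --timing sim/phantom_timing.tsv --labels sim/phantom_labels.nii.gz \
    --config cfg.yaml --rois 17,18 --out out/
```

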