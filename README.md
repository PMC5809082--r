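# cortmicro

Cortical microstructure mapping from multi-shell diffusion MRI and
quantitative histology, for preclinical (rodent) stress and depression
studies.

Chronic-mild-stress experiments compare cortical regions of interest --
motor (MC), somatosensory (SC), auditory (AC) and visual (VC) cortex --
across control, anhedonic (stress-susceptible) and resilient animals, using
ex-vivo diffusion MRI backed by immunohistochemistry. cortmicro implements
that entire analysis as tested, reusable R code:

* **Diffusion tensor (DTI)**: weighted log-linear fit; mean diffusivity
  `MD = (lambda1 + lambda2 + lambda3)/3` and fractional anisotropy
  `FA = sqrt(3/2 * sum((lambda_i - MD)^2) / sum(lambda_i^2))`.
* **Diffusion kurtosis (DKI)**: conventional non-linear least squares of
  `ln S = ln S0 - b D_app(n) + (b^2/6) MD^2 What(n)` on the b <= 4.5
  ms/um^2 shells, with the six reported summaries MK, AK, RK
  (directional averages of `K_app(n) = MD^2 What(n) / D_app(n)^2`) and
  MKT, W_L, W_T (eigenframe contractions of the kurtosis tensor W).
* **Two-compartment neurite-density model**: Levenberg--Marquardt fitting
  of `S(b,g) = s0 [ neu Int f(n) exp(-b D_L (g.n)^2) dn +
  (1-neu) exp(-b D_eff) ]` -- stick compartment with a spherical-harmonic
  orientation distribution f, plus an isotropic extra-neurite compartment
  -- yielding neurite density `neu`, intra-neurite diffusivity `D_L` and
  extracellular diffusivity `D_eff` per voxel.
* **ROI statistics**: slice-wise ROI aggregation into a tidy cohort table;
  REML linear mixed model `value ~ group + (1 | animal)` with Satterthwaite
  F-tests, gatekept pairwise contrasts and Benjamini--Hochberg FDR
  correction; 95% CIs on group means.
* **Histology**: DAB stain-positive area fractions (axonal NF-H, dendritic
  MAP2) with shape-based cell-body removal (eccentricity / equivalent
  diameter criteria on 8-connected, hole-filled components), and cortical
  thickness from calibrated line annotations.
* **Synthetic generators** for every input -- Rician-noise multi-shell
  voxels, hierarchical cohorts with planted group effects, stained
  micrographs, cortex montages -- with exact ground truth, so the whole
  chain is verifiable end to end.

Standard formats are used throughout: NIfTI-1 volumes (RNifti), FSL
bval/bvec or TSV b-tables, TIFF/PNG micrographs, CSV annotation and cohort
tables, YAML/JSON configuration.

## Worked example

Simulate one voxel on the study's 14-shell, 12-direction ex-vivo protocol,
fit the neurite model, then run the full simulate-fit-aggregate-test chain
on a cohort with a planted auditory-cortex D_eff deficit:

```r
library(cortmicro)

p <- default_protocol()
p
#> Diffusion protocol: 14 shells x 12 directions ( 157 frames )
#>   b [ms/um^2]: 0.0, 0.5, 1.0, 1.5, 2.0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 6.0, 7.0, 8.0
#>   Delta/delta: 15 / 5 ms

truth <- neurite_params(0.45, 1.2, 0.55,
                        odf_coeffs = cortmicro:::watson_odf_coeffs(3, c(0.4, 0.2, 1)),
                        s0 = 100)
ds  <- dwi_dataset(array(simulate_voxel(truth, p), c(1, 1, 1, 157)), p)
fit <- fit_neurite(ds)
round(coef(fit)[, c("neu", "d_long", "d_eff", "rss")], 4)
#>    neu d_long d_eff rss
#> 1 0.45    1.2  0.55   0
```

The noiseless fit returns the planted neurite fraction (0.45), intra-neurite
diffusivity (1.2 um^2/ms) and extracellular diffusivity (0.55 um^2/ms)
exactly. A cohort with control D_eff = 0.60 and both stress groups at
0.48 um^2/ms in AC (between/within-animal SD 0.03, stress-group variance
inflation 1.5, Rician SNR 50):

```r
eff <- data.frame(metric = "D_eff", roi = "AC",
                  group = c("control", "anhedonic", "resilient"),
                  mean = c(0.60, 0.48, 0.48),
                  between_sd = 0.03, within_sd = 0.03)
out <- run_cohort_chain(cohort_effect_spec(eff, mode = "maps", seed = 42))
out$result
#> D_eff in AC: F(2, 18) = 29.801, p = 1.944e-06
#>      group  estimate    ci_low   ci_high
#>    control 0.6191880 0.5854440 0.6529321
#>  anhedonic 0.4411314 0.4046837 0.4775792
#>  resilient 0.5046046 0.4730399 0.5361693
#> Pairwise contrasts (BH-adjusted):
#>               contrast    estimate  ...        p_fdr
#>    control - anhedonic  0.17805663  ... 1.717960e-06
#>    control - resilient  0.11458345  ... 8.860494e-05
#>  anhedonic - resilient -0.06347319  ... 1.273716e-02
```

Both control-vs-stress contrasts are FDR-significant: the planted
extracellular-diffusivity deficit survives voxel-wise fitting, slice-wise
aggregation and the mixed-model test. `group_summary(out$table, "D_eff",
"AC")` adds per-group descriptive CIs that reflect the planted stress-group
variance inflation.

The kurtosis side has analytic anchors, e.g. an isotropic two-site mixture
(f = 0.5, D = 0.5 and 1.5 um^2/ms) has excess kurtosis
`K = 3 Var(D) / mean(D)^2 = 0.75`, and the fit returns it from simulated
signal:

```r
mix <- list(d6 = c(1, 1, 1, 0, 0, 0), w15 = cortmicro:::w15_isotropic(0.75))
kfit <- fit_dki(dwi_dataset(array(simulate_voxel(mix, p), c(1, 1, 1, 157)), p))
round(kurtosis_metrics(kfit), 4)
#>   MK   AK   RK  MKT  W_L  W_T
#> 0.75 0.75 0.75 0.75 0.75 0.75
```

`run_pipeline(pipeline_config(...))` orchestrates the same stages from a
YAML/JSON configuration over real or simulated inputs and writes a results
CSV, a JSON audit summary, per-ROI forest figures and a log.

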