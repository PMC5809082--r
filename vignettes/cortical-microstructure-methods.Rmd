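---
title: "Models and methods for cortical microstructure mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for cortical microstructure mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortmicro)
```

cortmicro implements a complete analysis chain for ex-vivo multi-shell
diffusion MRI of rodent cortex with accompanying quantitative
immunohistology: voxel-wise model fitting (diffusion tensor, diffusion
kurtosis tensor, two-compartment neurite-density model), ROI-level
mixed-effects group inference, and DAB stain quantification. Because the
kind of animal data this pipeline targets is rarely shareable, every input
has a synthetic generator with known ground truth, and the package's
quantitative guarantees are stated against those generators. This vignette
records the models, the estimator choices, the defaults that fill gaps a
methods section typically leaves open, and what the synthetic experiments
do and do not demonstrate.

## The acquisition model

All fitting is organised around a `diffusion_protocol`: shell b-values in
ms/um^2, one fixed set of gradient directions shared by all shells, and the
pulse timing. `default_protocol()` is the ex-vivo scheme the package is
designed around: 14 b-values (0, 0.5, ..., 4.5, 5, 6, 7, 8 ms/um^2) with 12
fixed directions at 250 um isotropic resolution, Delta/delta = 15/5 ms.

Two conventions are worth stating explicitly:

* **Units.** The canonical internal unit is ms/um^2. `read_btable()`
  interprets b-values as s/mm^2 (and divides by 1000) whenever
  `max(b) >= 100`, which separates the two dialects unambiguously and
  avoids silent 1000x errors.
* **The 12-direction set** is the icosahedron-vertex scheme (six antipodal
  axes). No direction table is published with the acquisition description;
  the icosahedral set is the classic fixed-12 preclinical choice and has a
  property that matters below: its vertices integrate quartic polynomials
  exactly (a spherical 5-design).

All b = 0 frames are averaged into one effective measurement before any
fit; this is a pure variance reduction and makes results independent of
where the b = 0 frames sit in the acquisition order.

## Diffusion and kurtosis tensor estimation

The diffusion tensor is estimated by weighted linear least squares on the
log-signal (weights equal to the squared predicted signal, one refinement
pass). This deterministic estimator tracks non-linear least squares closely
at the SNR of long ex-vivo acquisitions while being orders of magnitude
cheaper. MD and FA follow the standard eigenvalue formulae, with FA clamped
to [0, 1] and defined as 0 whenever MD < 1e-6 um^2/ms (the 0/0 guard).
Axial and radial diffusivities are available from the eigensystem but are
not emitted as maps. By default a pipeline that also fits the kurtosis
tensor takes MD and FA from that joint fit (the b <= 4.5 subset) rather
than refitting a separate low-b tensor; `fit_dti()` remains available with
a configurable `b_max` for a pure Gaussian-regime fit.

The kurtosis model is the conventional quadratic cumulant expansion,

    ln S(b, n) = ln S0 - b D_app(n) + (b^2 / 6) MD^2 What(n),

fitted by Levenberg--Marquardt on the magnitude signal (analytic Jacobian),
initialised from the log-linear solution, on the shells with b <= 4.5
ms/um^2. The MD^2-scaled convention for W is used throughout, so
`K_app(n) = MD^2 What(n) / D_app(n)^2` and the bi-exponential closed form
`K = 3 Var(D) / mean(D)^2` holds as stated. No positivity or range
constraints are imposed; non-converged voxels keep the log-linear estimate
and are flagged.

**Rank deficiency and the minimum-norm convention.** Twelve directions
cannot span the 15 unique components of a fully symmetric rank-4 tensor
(six antipodal axes span only six), so on this protocol the kurtosis tensor
is identified only up to the design's null space. The package resolves this
deterministically: the log-linear system is solved by a pseudoinverse in
multiplicity-scaled coordinates, and the NLLS solution is projected back
onto the design's row space, which makes every reported W the
minimum-Frobenius-norm tensor consistent with the measured signals. Two
consequences follow. First, Gaussian signals always give exactly zero
kurtosis, and isotropic kurtosis is recovered exactly (the isotropic tensor
lies in the span of the icosahedral quartics -- this is where the 5-design
property enters). Second, for a general anisotropic W only the apparent
kurtosis along the measured axes is faithful; eigenframe contractions of W
from this protocol should be read with that caveat. Fits on direction sets
with 15 or more independent quartic signatures recover arbitrary (D, W)
pairs to machine precision.

Scalar summaries: MK is the spherical mean of `K_app` computed by a
Gauss--Legendre x uniform-azimuth product quadrature (24 x 48 = 1152 nodes;
spectrally accurate for these smooth rational integrands, and verified in
the tests against a 10,000-point equal-area oracle grid); AK is `K_app`
along the principal diffusion eigenvector; RK is the azimuthal mean over
the perpendicular plane (64 angles, exact for trigonometric polynomials of
this degree). The tensor summaries MKT, W_L and W_T are contractions of W
in the diffusion eigenframe. Near-degenerate leading eigenvalues
(lambda1 - lambda2 < 1e-9) are resolved by picking the eigenvector with the
largest |z| component, with signs fixed so the largest-magnitude entry is
positive -- an arbitrary but deterministic tie-break.

## The two-compartment neurite-density model

The biophysical model splits the signal into a stick compartment (axons and
dendrites: zero transverse diffusivity, longitudinal diffusivity `D_L`)
whose orientations follow a distribution f(n), and an isotropic Gaussian
extra-neurite compartment with scalar diffusivity `D_eff`:

    S(b, g) = s0 [ neu * Int f(n) exp(-b D_L (g.n)^2) dn
                   + (1 - neu) exp(-b D_eff) ].

`neu` is a T2-weighted signal fraction, not a volume fraction, and is
documented as such. The extra-neurite compartment is deliberately a single
free scalar per voxel -- the model family this package follows treats
compartmental diffusivities as estimable, in contrast to fixed-diffusivity
NODDI-style parametrisations. The orientation integral is evaluated by
expanding the stick kernel in even Legendre bands (coefficients by 64-point
Gauss--Legendre quadrature, exact well beyond the bands used) and
contracting with the ODF's real spherical-harmonic coefficients (bands 0,
2, 4 by default; order 2 is exposed for reduced direction sets). The l = 0
coefficient is fixed at 1/sqrt(4 pi) so the ODF integrates to one.

Fitting is Levenberg--Marquardt on the magnitude signal over the full
14-shell range, with bounds enforced by smooth reparametrisation (logistic
for `neu`; diffusivities mapped to [0, 3] um^2/ms, a generous ex-vivo
bound) and a 3 x 3 x 3 multi-start grid over
neu in {0.2, 0.5, 0.8}, D_L in {0.5, 1.0, 1.5}, D_eff in {0.3, 0.7, 1.1}
um^2/ms. By default all 27 starts are refined (in order of initial
residual, with an early exit once a start reaches the noise floor, so
noiseless fits stay cheap). The full grid is not a luxury: the model has a
near-degenerate ridge when the ODF is nearly isotropic and D_L falls below
D_eff -- the two compartments can almost trade roles -- and only a wide
multi-start reliably escapes the resulting local minimum. `refine_top`
trades that robustness for speed where thousands of voxels are fitted under
a strong planted effect (the cohort experiment uses 3). The objective is plain Gaussian least squares on
magnitude data; a Rician-bias floor term is deliberately not included by
default, and the resulting small downward bias of `D_eff` at SNR 50
(about -0.03 um^2/ms at the default ground truth) is shared by all groups
and does not move group contrasts.

With 12 directions (six axes) the l = 4 ODF band (nine coefficients) is
underdetermined. The scalar parameters remain identifiable through the
shell dependence of the kernel, so the fit reports identifiability per
voxel by checking whether any null direction of the Jacobian at the optimum
touches (s0, neu, D_L, D_eff); a voxel is additionally flagged
non-identifiable when the fitted `neu` falls outside [0.02, 0.98] (an
absent compartment leaves its diffusivity meaningless). ODF coefficients
are left unconstrained; the fraction of ODF mass below zero is recorded as
a per-voxel diagnostic rather than being clamped away.

## ROI statistics

Parameter maps are aggregated per animal x ROI x metric into slice-wise
cross-section means over valid (fitted) voxels -- the slice is the
replicate unit for d-MRI metrics, giving the random effect repeated
measures to absorb; for histology the replicate is the section or montage.
The mixed model is `value ~ group + (1 | animal)`, fitted by REML, with the
overall group F-test using Satterthwaite denominator degrees of freedom and
alpha = 0.05. When the random-effect variance estimate is singular, or each
animal contributes a single observation, the model degrades to a
fixed-effects one-way ANOVA and the result is flagged. Post-hoc pairwise
contrasts run only when the overall test is significant (gatekeeping), use
Satterthwaite degrees of freedom, and are Benjamini--Hochberg adjusted
within the three-contrast family of each (metric, ROI); the family
definition is configurable.

Model-based group-mean CIs from the homoscedastic mixed model differ
between groups only through group size. Group-specific dispersion -- the
quantity a per-group error-bar figure shows, and the quantity of interest
when stress groups respond heterogeneously -- is therefore reported
separately by `group_summary()` as a per-group t-interval on animal means.

## Synthetic generators: what they emulate

* `simulate_voxel()` produces forward-model signals with Rician noise
  (magnitude of signal plus complex Gaussian, per-channel SD s0/SNR) --
  the correct magnitude-MRI noise model, verified in the tests by its
  moments.
* `simulate_cohort()` draws the hierarchy animal effect ~ N(0, between_sd),
  replicate = group mean + animal effect + N(0, within_sd), with both SDs
  multiplied by `variance_inflation` (default 1.5) in the stress groups --
  heterogeneous stress response inflates both how animals differ and how
  slices within an animal differ. Group sizes default to 7 control / 6
  anhedonic / 8 resilient, the post-exclusion sizes of the study design.
  The default effect template encodes only the qualitative finding
  structure (lower D_eff in auditory cortex for both stress groups; higher
  FA and axonal density and lower thickness in motor cortex); all
  magnitudes are configuration, since no effect sizes are published in
  text. Four replicates per animal reflect the four 250-um slices spanning
  the 1-mm anatomical window. In map mode each replicate's D_eff
  parametrises the forward model and voxels are simulated at SNR 50 with an
  order-2 axially symmetric Watson-type ODF (concentration 3); four voxels
  per ROI cross-section stand in, at feasible cost, for the tens of voxels
  of a real cross-section.
* `synth_micrograph()` renders dark quasi-circular somata and dark
  random-walk polylines on a noisy white background, with processes kept
  off a margin around somata so the rendered truth classes stay disjoint;
  the truth table records exact rendered pixel fractions.
* `synth_cortex_montage()` builds a two-boundary band of known thickness
  with optional sinusoidal undulation and emits five measurement lines per
  ROI along the local normal of the pial boundary.

What passing these experiments shows: the estimators invert their own
forward models across the admissible parameter space, the test statistics
are calibrated, and the image-processing chain recovers planted geometry.
What it does not show: robustness to real-tissue features the generators do
not emulate -- partial volume at ROI boundaries, B0/eddy distortions
(absent ex vivo but real in vivo), staining gradients and section damage,
anatomically realistic fibre configurations, or spatial noise correlation.
Conclusions about real data require the usual quality control that the
pipeline's diagnostics (fit flags, ODF negativity fraction, empty
cross-section warnings) are designed to support.

## Histology quantification choices

"Thresholded to 30% relative to the signal level" is interpreted as 30% of
the per-image post-enhancement intensity range -- the only reading that is
well defined on [0, 1]-normalised images -- and the threshold is echoed
into the run report. Luminosity scaling divides by the 99th-percentile
luminance of the least-stained decile of pixels; stain intensity is one
minus normalised luminance; contrast enhancement stretches the 1st-99th
percentiles to [0, 1]; a batch processed with `histo_batch_params()` shares
one parameter set across all images. Cell-body criteria default to
eccentricity <= 0.85, equivalent diameter 6-25 um and area >= 20 px --
typical neuronal soma scales; no published cut-offs exist, so all four are
configuration and are logged. Components are 8-connected and are hole-filled
before shape measurement, because DAB-stained somata contain unstained
counterstained nuclei that would otherwise split or distort the shape
estimate. The dendritic (MAP2) path is the identical chain under its own
enhancement/criteria profile.

## Numerical and engineering choices

* Tolerances: pseudoinverse rank cut at 1e-10 relative; eigenvalue
  tie-break at 1e-9; ODF normalisation checked at 1e-6.
* Every generator is a pure function of its specification and seed; the
  caller's RNG stream is saved and restored.
* Problem sizes in the verification experiments (five Gaussian tensors, 100
  oracle tensors, a 100-point Latin hypercube, 200 noise replicates, 2,000
  null simulations, 100 seeded cohort runs with 21 animals x 4 slices x 4
  voxels) were chosen once as the smallest designs that pin each property
  down tightly.
* The experiment that reruns the full chain across 100 seeds uses the
  order-2 fitting configuration matched to the generator's order-2 ODF and
  `refine_top = 3`; the defaults (order 4, `refine_top = 5`) remain the
  recommendation for real data.

## Known limitations

* Eigenframe kurtosis contractions from the 12-direction protocol inherit
  the minimum-norm convention described above; they are exact for the
  isotropic and Gaussian cases and approximations otherwise.
* The per-group CI-width comparison in the cohort experiment is
  intrinsically noisy at 6-8 animals per group: the width of a t-interval
  on so few animal means has a coefficient of variation near 30%, so even a
  1.5-fold planted SD inflation leaves a nontrivial fraction of runs in
  which a stress-group interval is narrower than control. The experiment
  reports the observed rate rather than forcing it.
* No spatial regularisation anywhere: every voxel is fitted independently,
  matching the voxel-wise analysis the pipeline reproduces.
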