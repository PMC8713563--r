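---
title: "Voxel-wise intrinsic connectivity analysis with sex-by-exposure interactions: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise intrinsic connectivity analysis with sex-by-exposure interactions: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsicd)
```

# The scientific problem

Resting-state functional MRI measures spontaneous BOLD fluctuations;
correlations between voxel time series ("resting-state functional
connectivity", rsFC) delineate intrinsic brain networks. This package
implements a complete analysis chain for asking how a subject-level exposure
count — here, the number of traumatic events (TEs) reported on a nine-item
binary screen — relates to voxel-level connectivity, and whether that
relationship differs by sex. The chain is: questionnaire scoring and
participant-level quality control; preprocessing of registered 4D volumes;
the voxel-wise *intrinsic connectivity distribution* (ICD) summary; a
voxel-wise regression with a sex-by-exposure interaction and cluster-extent
permutation correction; and seed-based network definition scored against a
seven-network reference parcellation.

Because suitable raw data are controlled-access, the package ships a
synthetic cohort generator that reproduces the statistical structure the
inference relies on, with planted ground truth, so every stage is testable
end to end.

# The intrinsic connectivity distribution

For a gray-matter voxel $v$, compute the Pearson correlation of its
(preprocessed, censor-filtered) time series with every other gray-matter
voxel, discard negative values, and form the empirical survival function of
the positive correlations on the threshold grid
$\tau \in \{0.01, 0.02, \ldots, 0.99\}$:

$$S_v(\tau) = \frac{\#\{u \ne v : r_{uv} > \tau\}}{\#\{u \ne v : r_{uv} > 0\}}.$$

The ICD summarises $S_v$ by nonlinear least squares against the
stretched-exponential survival model

$$S(\tau) = \exp\!\left(-(\alpha \tau)^{\beta}\right), \qquad \alpha, \beta > 0.$$

$\alpha$ is an inverse scale: a voxel whose survival curve is uniformly
higher (more strong connections — higher connectivity) receives a *smaller*
$\alpha$. $\beta$ shapes the decay. This parameterisation was chosen for
that directionality; the model sits behind a single interface
(`icd_model()`, `fit_icd()`) so the functional form is pluggable.

Numerical choices:

* The fit minimises the unweighted sum of squares on the survival scale
  over the full $\tau$ grid (no histogram binning, hence no bin-width
  choice; grid step 0.01).
* The primary starting point comes from the exact linearisation
  $\log(-\log S) = \beta \log \alpha + \beta \log \tau$ computed on the
  strictly interior survival values; when that is unusable the fit starts
  from $(1, 1)$, and a small restart lattice
  ($\alpha \in \{0.5, 1, 2, 4\}$, $\beta \in \{0.5, 1, 2\}$) guards
  against non-convergence. Tests verify against an exhaustive grid-search
  oracle that the optimiser reaches the global optimum.
* Curves with fewer than five survival values strictly inside $(0, 1)$
  (e.g. a curve identically 1) are explicit fit failures, propagated as
  `NA` — never silent zeros. A subject aborts when more than 20% of voxels
  fail.
* Voxels are processed independently in chunks (bounded memory); results
  are bit-identical regardless of chunk size.

Fitted $\alpha$/$\beta$ maps are then smoothed with a mask-renormalised
4 mm FWHM Gaussian kernel, failed voxels excluded from the normalisation.

# Preprocessing on registered volumes

The package assumes volumes are already aligned to a common grid
(registration, slice timing and anatomical processing are out of scope).
Stage order is fixed and recorded: truncate (drop the first four frames) →
censor → smooth → motion/frequency GLM → tissue-based regression.

**Censoring.** A frame is censored when the Euclidean norm of the
frame-to-frame translation difference strictly exceeds 0.3 mm (the later
frame of the pair is removed) or when more than 10% of voxels are outliers
in that frame. An outlier is a value more than three MAD-based sigmas from
the voxel's temporal median; on clean Gaussian data the outlier fraction
per frame is ~0.3%, far from the 10% gate, so the false-censor rate is
negligible. "Average motion per TR" is the mean framewise displacement,
computed from translations only by default (the rotation-to-mm conversion
on a 50 mm sphere is available via `motion_trace(include_rotation=)`).

**Smoothing.** Separable Gaussian convolution with
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis, renormalised over the
mask (`conv(x \cdot m) / conv(m)`) so no signal bleeds across the mask
boundary. In the pipeline the 6 mm kernel is applied *within the
gray-matter mask only*: at desk-scale geometry, smoothing across tissue
boundaries contaminates the white-matter mean and ventricle components
with gray-matter signal and roughly doubles between-subject noise in the
ICD maps. `smooth_gaussian()` accepts any mask if whole-brain smoothing is
wanted.

**Band-limiting nuisance GLM.** Per voxel, OLS over the non-censored
frames on an intercept, the six motion parameters, their backward
differences, and sine/cosine regressors for all frequencies outside
0.01–0.08 Hz; the residuals are the cleaned series. Implementing the
band-pass as out-of-band regressors inside the GLM keeps it exact under
censoring. Below the low cutoff the regressor frequencies are spaced at
*half* the DFT bin width: slow drifts generally fall between DFT bins, and
with the pure DFT grid a 0.005 Hz drift would retain ~20% of its
amplitude, whereas the half-bin set reduces it below 1% while keeping
≥ 95% of in-band signal. Designs left rank-deficient by heavy censoring
are flagged as errors, never silently fit.

**Tissue-based regression.** The white-matter and ventricle masks are
eroded by one voxel (6-connected, single pass; fallback to the uneroded
mask with a warning if erosion empties it). The regressors are the mean
eroded-white-matter series and the first three principal-component time
courses (unit variance) of the eroded ventricle voxels; fewer components
are used, with a message, when the mask is small. Both are removed from
every gray-matter voxel by OLS over non-censored frames.

# Group model and inference

Per voxel, the smoothed ICD parameter (alpha by default; beta supported)
is regressed on six terms: intercept, capped exposure count
$t \in \{0,1,2,3\}$, a male indicator (female = 0), the sex-by-exposure
product, age (years), and maternal education (years). With this coding the
exposure coefficient is the *female* slope and the interaction coefficient
is the male-minus-female slope difference, so the male slope is their sum
(`interaction_slopes()` returns both with standard errors).

**Cluster-extent correction.** Voxels with two-sided $p < 0.001$ on the
tested term form 6-connected components (18/26 configurable). Family-wise
error is controlled by a Freedman–Lane max-cluster permutation null: the
reduced model (without the tested term) is fitted, its residuals are
row-permuted and added back to the reduced fit, the full model is refitted
on the surrogate, and the maximum supra-threshold cluster statistic is
recorded; `n_perm` defaults to 1000 (500 in the pipeline
configuration) and at least 100 is enforced. The
cluster statistic is the extent with ties between equal-sized clusters
broken by cluster mass (the summed excess of $|t|$ over the threshold,
squashed into $(0,1)$ so a larger extent always dominates). The tie-break
matters: at desk scale supra-threshold clusters are small integers, and a
purely integer-valued extent makes the permutation test conservative
(empirical family-wise rate ~0.013 at nominal 0.05 in our null
simulations); the continuous statistic restores near-exact level. Clusters
with permutation-corrected $p \le 0.05$ are reported with size, peak voxel
(largest absolute coefficient, ties to the smallest linear index, mm
coordinates), hemisphere of the peak, and the average in-cluster
coefficient.

Voxel tests are two-sided. The permutation substitutes for parametric ACF
cluster correction because it is self-contained and assumption-light; the
method and its settings are recorded in the result metadata.

**Seed-based networks.** Each significant cluster seeds a connectivity
map per subject: mean seed series over non-censored frames, Pearson
correlation to every gray-matter voxel, Fisher $z = \operatorname{atanh}(r)$
with $|r|$ clipped at $1 - 10^{-7}$. A one-sample two-sided t test per
voxel across subjects, with Benjamini–Hochberg FDR over gray-matter
voxels, defines the network mask as voxels passing both thresholds and
(by default) carrying positive mean $z$. The published-scale thresholds
($p < 10^{-44}$, FDR $< 3\times10^{-16}$) presuppose many hundreds of
subjects; they are configuration defaults in spirit only — desk-scale
cohorts must use looser values (the pipeline default is $p < 10^{-6}$,
FDR $< 10^{-4}$), which is why both are explicit configuration keys.
Overlap with a seven-label reference parcellation is reported as the
percentage of network voxels per label (summing to 100 with the unlabeled
remainder), and the pairwise overlap of network $B$ with network $A$ is
$|A \cap B| / |B| \times 100$.

# The synthetic cohort

The generator (`sim_design()`, `simulate_cohort()`) emulates the features
the inference depends on, not scanner physics.

**Covariates.** Ages uniform on 8–21 years; sex Bernoulli with female
fraction 0.578; nine binary exposure items that are conditionally
independent given a latent exposure-prone class (70% of subjects; per-item
rate within the class ≈ 0.12, solving for an overall 47.8% probability of
at least one event). The latent class reflects the empirical clustering of
traumatic events within subjects; with marginally independent items a
60-subject cohort would frequently contain no multi-event subjects at all,
leaving the exposure slope unidentified. The implied capped-count
distribution is roughly 52/27/15/6%. Maternal education sits around 14
years, declining 0.4 years per raw event count; a 12.8% brain-injury flag
and rare block-missing items/education exercise the QC gates.

**Images.** Each voxel community (somatomotor-like, DMN-like) has a shared
factor: voxel $i$ in community $c$ follows
$\sqrt{\rho_c}\, g_c(t) + \sqrt{1-\rho_c}\, e_i(t)$, so the
within-community correlation equals $\rho_c$ exactly in the generating
model and the covariance is positive semi-definite for any
$\rho_c \in [0, 1)$. Exposure enters linearly:
$\rho_c = \mathrm{baseline} + \mathrm{slope}_c \cdot t$, clipped to
$[0, 0.95]$ with clip events counted (with clipping disabled, an
out-of-range request errors naming the subject). The somatomotor-like
community uses one slope for everyone (negative by default: connectivity
falls with exposure, so fitted alpha rises); the DMN-like community uses
sex-specific slopes of opposite sign. Background gray matter is generated
unstructured (coupling 0): with hundreds of weakly coupled background
voxels, background ICD would otherwise dominate the communities' (many
weak correlations outweigh few strong ones) and the intended
"community = high connectivity" ordering would invert. White-matter
voxels share a band-limited nuisance source, ventricle voxels mix three
more; all four are also mixed into gray matter with random loadings of
scale 0.3 so that skipping tissue regression measurably biases the ICD.
White observation noise (SD 0.3) and a motion-locked global artifact
complete the signal. Motion traces are random walks with displacement
spikes; ~12% of subjects get globally scaled motion and are meant to fail
QC.

**Scale.** Default grid 20×20×12 voxels at 5 mm — a desk-scale stand-in
that keeps 3D adjacency semantics while an end-to-end cohort runs in
minutes. The 5 mm voxel size is deliberate: with 3 mm voxels the 6 mm
kernel averages ~27 neighbours, pushes within-community correlations into
saturation (0.55 becomes ~0.9) and flattens the alpha response to
coupling, while at voxel-scale kernels the response stays nearly linear;
5 mm keeps enough smoothing for spatially coherent statistic maps without
the saturation. TR defaults to 3 s with 124 frames (a 6.2-minute scan;
four frames are dropped in preprocessing).

**Effect sizes.** The planted defaults (baseline coupling 0.55, main
slope −0.15 per event, DMN slopes +0.12 male / −0.12 female) are
deliberately larger than published effect sizes (~0.066 alpha units per
event found with n ≈ 900): at 124 frames the between-subject noise of
community-level alpha is dominated by correlation-sampling noise that is
*shared* across a community (~0.3 alpha units) and does not average away
over voxels, so a 60-subject demonstration needs proportionally larger
effects to have power. This is a deliberate scaling of the study design to
desk size; passing tests therefore demonstrate correctness of the
machinery, not that effects of the published magnitude are detectable at
n = 60.

**What the generator does not emulate.** Scanner physics, slice timing,
susceptibility artifacts, anatomical variability, registration error,
non-Gaussian noise, and genuinely nonlinear exposure-connectivity
relationships. Passing tests show the pipeline recovers structure from
data satisfying its model assumptions; they cannot show robustness to
violations real data may exhibit.

# Quality control semantics

Raw exposure count is the unweighted item sum; the regression code caps it
at 3 (three or more events form one group). Exclusion gates run in a fixed
order — mean motion per TR, censor fraction, optional co-registration
flag, brain injury, missing trauma items, missing maternal education — and
each excluded subject carries only the *first* reason triggered, so
per-reason counts are disjoint. Both motion gates use strict inequality:
exactly 0.3 mm mean motion or exactly a 30% censor fraction passes.
Re-running QC on the included set excludes nobody.

# Problem sizes used in validation

The test-suite simulations were sized to be informative while keeping a
full run on one CPU comfortable: model-recovery and dominance checks use
100 curves/pairs; the connectivity-ordering check uses 100 single-subject
simulations at 124 frames; null calibration of the cluster correction uses
200 datasets of 100 subjects each with 500 permutations; planted-cluster
detection uses 10 cohorts of 300 subjects; the interaction-coverage check
uses 100 cohorts of 300 subjects; the end-to-end demonstration runs the
default 60-subject cohort twice and compares outputs byte for byte.

# Known limitations

* Appendix-level details of the original ICD implementation (exact model
  form and fitting algorithm) are not public in the text available to us;
  the stretched-exponential survival model is our choice, made pluggable.
* The permutation null assumes exchangeable reduced-model residuals
  (homoscedastic subjects); heavy-tailed subject noise would need a
  studentised variant.
* No surface-based analysis, no TFCE, no mixed-effects or robust voxel
  models, no global-signal regression, no atlas-based anatomical labels
  for clusters (cluster masks are exported for external labelling).
* Affines must match exactly across inputs; there is no resampling.
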