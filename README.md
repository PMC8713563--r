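# rsicd

Voxel-wise resting-state functional connectivity analysis built around the
**intrinsic connectivity distribution (ICD)**, with sex-by-exposure
interaction mapping, cluster-extent permutation correction, and seed-based
network definition — plus a fully synthetic resting-state cohort generator
so the entire chain is testable without access to restricted imaging data.

## Who this is for

Researchers who want to relate a subject-level exposure count (here: the
number of traumatic events from a nine-item binary screen, capped at 3) to
voxel-level functional connectivity, and to ask whether the association
differs between the sexes. The package implements the full analysis chain
on registered NIfTI volumes: questionnaire scoring and participant QC,
fMRI preprocessing (frame censoring, masked smoothing, motion +
band-limiting nuisance GLM, tissue-based regression), the ICD voxel
summary, a voxel-wise GLM with interaction and permutation cluster
correction, and network overlap scoring against a 7-network reference
parcellation.

## The model at the core

For each gray-matter voxel, the distribution of its positive correlations
with all other gray-matter voxels is summarised by the empirical survival
function S(τ) on τ = 0.01, …, 0.99, fitted by nonlinear least squares with
the stretched-exponential decay model

    S(τ) = exp( −(α·τ)^β ),   α, β > 0

A voxel with uniformly more strong connections — higher connectivity —
receives a **smaller α**; β shapes the decay. Smoothed α maps are then
regressed per voxel on

    α_v ~ intercept + TE + sex + sex:TE + age + maternal education

with female coded 0, so the TE coefficient is the female slope and the
interaction coefficient is the male-minus-female slope difference.
Clusters of voxels with two-sided p < 0.001 are retained when they survive
a Freedman–Lane max-cluster permutation test at α = 0.05, and each
significant cluster seeds a group connectivity network (Fisher-z maps,
one-sample t test, FDR) that is scored against the reference parcellation.

## Worked example

```r
library(rsicd)

cfg <- pipeline_config(seed = 2024)      # 60 simulated subjects, 20x20x12 grid
res <- run_pipeline(cfg, out_dir = "demo_run")

res$qc$counts                 # exclusions per reason
res$clusters$te               # significant main-effect clusters
res$overlaps[[1]]             # parcellation overlap of network 1
```

A run prints its stage progress and writes `qc_report.tsv`,
`demographics.tsv`, `clusters_te.tsv`, `clusters_sex_te.tsv`,
`overlap.tsv`, `pairwise_overlap.tsv` and `manifest.json` (the fully
resolved configuration) into `demo_run/`. With seed 2024 the run prints
(the pipeline is deterministic given the seed, so your numbers match
exactly):

```
#> simulate: 60 subjects on a 20x20x12 grid
#> qc: 49 of 60 subjects included
#> icd: fitting parameter maps for 49 subjects
#> glm: cluster correction for term 'te'
#> glm: cluster correction for term 'sex_te'

res$clusters$te
#> <cluster_result> term te: 9 significant cluster(s); null cluster-statistic threshold 2.16 (500 permutations)
#>   cluster size hemisphere peak_x peak_y peak_z average_effect corrected_p
#> 1       1   22       Left     20     45     30         0.3736    0.003992
#> 2       2   13      Right     50     30     50         0.3331    0.005988
#> 3       3   11       Left     20     20     30         0.3353    0.007984
#> ...

head(res$overlaps[[1]][3:4, ])
#>       network label n_voxels  percent
#> 3 te_cluster1     2      245 88.44765
```

Reading the tables: every main-effect cluster carries a *positive* average
TE coefficient on α (~0.25–0.40 per event) — connectivity decreases as
exposure increases, the planted direction — and the network seeded from
cluster 1 lands 88.4% on reference label 2, the somatomotor-like network.
The interaction clusters (`res$clusters$sex_te`) all carry negative
effects: males' α falls relative to females' with increasing exposure,
the planted sex-specific pattern in the DMN-like community. Cluster
coordinates are in mm via the shared affine; `corrected_p` is the
permutation-corrected cluster p value.

Single-stage use is equally supported, e.g.

```r
curve <- voxel_correlations(vol, gm_mask, voxel = c(10, 9, 6))
fit <- fit_icd(curve)
coef(fit)        # alpha, beta
plot(fit)        # empirical survival + fitted decay
```

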