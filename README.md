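# petsarc

Quantitative FDG-PET analysis for pediatric bone sarcomas (Ewing sarcoma
and osteosarcoma): lesion segmentation, radiomic feature extraction at
baseline and after neoadjuvant chemotherapy, metabolic response
classification, and prognostic survival screening — with a synthetic
phantom and cohort generator so the whole pipeline runs and is verifiable
without patient data.

## What it computes

For a lesion VOI on a SUV volume (NIfTI in, voxel spacing from the
header):

* **Intensity / volume** — SUVmax, SUVmean; SUVpeak as the hottest
  1-cm³ spherical mean, maximized over candidate centers, with radius
  r = (3·1000/4π)^(1/3) ≈ 6.204 mm; MTV = N·v_voxel/1000 (mL);
  TLG = SUVmean · MTV.
* **Heterogeneity** — 64-level quantization, then from grey-level matrices
  aggregated over the 13 unique one-voxel displacement directions:
  GLCM homogeneity Σ p(i,j)/(1+|i−j|), entropy −Σ p log₂ p,
  dissimilarity Σ |i−j| p(i,j); GLRLM HGRE = (1/N_r) Σ r(i,l) i²;
  GLSZM ZLNU = (1/N_z) Σ_s (Σ_i z(i,s))², SZHGE = (1/N_z) Σ z(i,s) i²/s².
* **Shape** — elongation (principal-axis bounding-box edge ratio; 1 =
  maximal symmetry), sphericity π^{1/3}(6V)^{2/3}/A, and compactness
  V/(√π A^{3/2}), with A and V measured on one marching-tetrahedra
  iso-surface mesh.
* **Segmentation** — iterative adaptive thresholding
  T_{k+1} = α·mean(SUV over region) + β·background from
  T₀ = 0.4·SUVmax(local), with a typed "not delineable" signal and a
  baseline-VOI fallback for vanished post-therapy lesions.
* **Response** — PERCIST-style CMR/PMR/SMD/PMD from paired SUVpeak
  (30% and 0.8 SUV margins), and the histologic responder dichotomy from
  the Salzer-Kuntschik grade (I–III vs IV–VI).
* **Prognosis** — univariate and screened multivariate Cox
  proportional-hazards models (Efron ties) of PFS/OS, Spearman correlation
  of feature deltas with the regression grade, and detection
  sensitivity/specificity with exact binomial intervals.

## Worked example

A synthetic baseline/post-chemotherapy pair with a 65% uptake reduction
and 50% volume reduction, segmented and measured:

```r
library(petsarc)

spec <- phantom_spec(grid_shape = c(36, 36, 36), spacing = c(2, 2, 2),
                     semi_axes = c(18, 12, 12), lesion_suv = 9,
                     background_suv = 0.8,
                     texture_pattern = list(type = "blobs", count = 4),
                     noise_sd = 0.15, background_noise_sd = 0.08, seed = 11)
pair <- generate_response_pair(spec, uptake_scale = 0.35, volume_scale = 0.5)

seg  <- adaptive_segment(pair$baseline$volume, seed_voxel = c(18, 18, 18),
                         background = 0.9)
fb   <- lesion_features(pair$baseline$volume, seg)
round(fb, 3)
#>       suv_max      suv_peak      suv_mean           mtv           tlg
#>         9.352         8.928         7.055        11.072        78.108
#>   homogeneity       entropy dissimilarity          hgre          zlnu
#>         0.284         9.372         5.565       648.594       276.851
#>         szhge    elongation    sphericity   compactness
#>       577.098         1.545         0.962         0.050

post <- adaptive_segment(pair$post$volume, c(18, 18, 18), background = 0.9)
fp   <- lesion_features(pair$post$volume, post)
round(delta_percent(fb, fp), 1)
#>  delta_suv_max delta_suv_peak delta_suv_mean      delta_tlg      delta_mtv
#>          -61.6          -67.4          -64.5          -83.9          -54.6

percist_classify(fb[["suv_peak"]], fp[["suv_peak"]], background_ref = 0.9)
#> [1] "PMR"
```

The segmented baseline MTV (11.072 mL) equals the ground-truth mask volume
exactly on this noise level; the SUVpeak drop of 67% with a 6.0 SUV
absolute decrease crosses both PERCIST margins, hence partial metabolic
response.

For a full study — cohort simulation, per-patient phantom pairs on disk,
feature/delta/response/prognostics CSVs and a reproducible run manifest:

```r
cfg <- simulate_study("study_dir", n_patients = 60, seed = 1)
res <- run_study(cfg)
head(res$prognostics)
```

Survival screening on simulated cohorts with known hazard structure:

```r
cs  <- cohort_spec(n_patients = 400,
                   true_log_hr = c(lung_metastasis = log(5.684)),
                   censoring_fraction = 0.3, seed = 1)
fit <- cox_univariate(generate_cohort(cs), "lung_metastasis", "pfs")
fit$table[, c("term", "hazard_ratio", "ci_lower", "ci_upper", "p_value")]
```

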