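---
title: "Quantitative FDG-PET analysis for pediatric bone sarcomas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative FDG-PET analysis for pediatric bone sarcomas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petsarc)
```

## The problem

Pediatric Ewing sarcoma (EWS) and osteosarcoma (OST) are staged and
monitored with FDG-PET. Beyond visual reading, the scans support
quantitative markers: how avid the lesion is (SUVmax, SUVpeak, SUVmean),
how large its metabolically active volume is (MTV, TLG), how heterogeneous
the tracer distribution is inside it (texture features over grey-level
matrices), and what shape the lesion takes (elongation, sphericity,
compactness). Changes in these markers between the baseline scan and the
scan after neoadjuvant chemotherapy, together with the histologic
regression grade of the resected tumor (Salzer-Kuntschik I–VI), feed
response assessment; the baseline markers feed prognostic models of
progression-free and overall survival (PFS, OS).

`petsarc` implements that pipeline end to end — segmentation, feature
extraction, response classification, survival screening — plus a synthetic
phantom-and-cohort generator, so every stage can be exercised and verified
without access to patient scans.

## Volumes, masks, units

A study is a 3-D grid of body-weight-normalized SUV values (g/mL) with
anisotropic voxel spacing in mm ([suv_volume()]); the lesion is a binary
volume of interest on the same grid ([lesion_mask()]). Images and masks are
exchanged as NIfTI with the spacing read from the header. Coordinates are
voxel indices internally and are converted to physical mm only inside
geometric operations; orientation handling is limited to axis-aligned
volumes (a documented limitation — reorient before import if needed).

## Adaptive segmentation

`adaptive_segment()` delineates the VOI by iterative, contrast-adapted
thresholding. From an initial threshold $T_0 = t_0 \cdot \mathrm{SUVmax}_{loc}$
(the local maximum in a small window around the seed, default half-width 3
voxels), the algorithm alternates

$$R_k = \text{connected component of } \{v \ge T_k\} \text{ containing the seed},
\qquad T_{k+1} = \alpha \, \overline{\mathrm{SUV}}(R_k) + \beta \, b,$$

where $b$ is a caller-supplied background SUV (from a reference region),
until $|T_{k+1}-T_k|/T_k < \mathrm{tol}$. Defaults: $\alpha = 0.5$,
$\beta = 1$, $t_0 = 0.4$, tol $= 0.01$, 26-connectivity, at most 100
iterations. On a noise-free two-level lesion the fixed point is
$T^\* = \alpha L + \beta b$ for lesion level $L$, so any contrast above
$(\beta b)/(1-\alpha)$ is recovered exactly; tests verify volume recovery
within 10% for spheres down to 4:1 contrast. Two degenerate situations
raise a typed "lesion not delineable" condition rather than returning a
bad mask: no uptake above background at the seed, and an initial threshold
that does not exceed the background level (which would flood the
background — the typical post-chemotherapy situation when uptake has
normalized). Non-convergence within the iteration cap returns the current
mask flagged `converged = FALSE`.

The exact calibration of the adaptive method used on the clinical scanners
is not public; the scheme above is this package's fully specified stand-in
from the same family of contrast-adaptive thresholds, with every parameter
exposed. It is not claimed to reproduce any particular clinical
segmentation.

When a follow-up lesion is not delineable, `fallback_voi()` reproduces the
baseline VOI on the follow-up grid under a rigid integer translation
supplied by the caller (standing in for anatomical-landmark alignment);
deformable registration is out of scope. If the mean uptake inside the
fallback VOI does not exceed the background reference, the pipeline treats
the lesion as metabolically vanished: MTV and TLG are set to 0 (driving
ΔTLG to −100%) and the patient is flagged `no_residual_uptake`.

## Intensity and volume metrics

* `suv_max`, `suv_mean`: maximum and mean SUV over the VOI.
* `suv_peak`: the hottest 1-cm³ spherical mean. For every candidate center
  (each VOI voxel center) the mean is taken over all grid voxels —
  mask-unrestricted — whose centers lie within
  $r = (3 \cdot 1000 / 4\pi)^{1/3} \approx 6.204$ mm; the maximum such mean
  is returned. Maximizing over candidate centers is our reading of
  "centered on the highest-uptake part" and matches PERCIST practice; the
  stricter variant fixing the sphere at the SUVmax voxel is available via
  `mode = "fixed_at_max"` (ties resolved by maximizing, so the result is
  order-independent). For lesions smaller than the sphere the mean
  necessarily averages in background, so `suv_peak` can sit well below
  `suv_max` and its deltas are damped for shrinking lesions — the metric's
  intended noise robustness, not an artifact. `suv_max >= suv_peak` is not
  enforced as an invariant: it can fail at coarse spacing where the sphere
  holds few centers.
* `mtv` (mL): foreground voxel count × voxel volume / 1000. Exact by
  construction.
* `tlg` (mL·SUV): `suv_mean × mtv`, an identity maintained to floating
  precision.
* `delta_percent()`: $\Delta f = 100 (f_{post} - f_{pre})/f_{pre}$, signed.
  A zero baseline value leaves that delta undefined (NA, with a warning).

## Texture features

The VOI is quantized to $G = 64$ grey levels (the convention for these
features) by masked min–max binning:
$\ell(v) = \min(G, \lfloor G (v - v_{min})/(v_{max} - v_{min})\rfloor + 1)$,
a constant region mapping to level 1. Min–max (rather than fixed bin
width) makes all texture features invariant under positive affine
transforms of the raw intensities, which the tests verify; fixed-width
binning is available via `method = "fixed_width"`.

Three matrix families are aggregated over the 13 unique one-voxel
displacement directions of the 26-neighborhood (a single matrix per
family, not 13 averaged ones):

* **GLCM** — ordered voxel pairs at each displacement, accumulated in both
  orientations (symmetric by construction), then normalized. Features:
  homogeneity $\sum p_{ij}/(1+|i-j|)$, entropy $-\sum p_{ij}\log_2 p_{ij}$
  (bits; consistent with 64-level matrices), dissimilarity
  $\sum |i-j| p_{ij}$.
* **GLRLM** — maximal constant-level runs along each direction, confined
  to the mask (a mask gap breaks a run). HGRE
  $= \frac{1}{N_r}\sum_{i,l} r(i,l)\, i^2$.
* **GLSZM** — maximal 26-connected constant-level zones. ZLNU
  $= \frac{1}{N_z}\sum_s \big(\sum_i z(i,s)\big)^2$, SZHGE
  $= \frac{1}{N_z}\sum_{i,s} z(i,s)\, i^2 / s^2$.

The $N_r$/$N_z$ normalizations are the standard run-length/size-zone
conventions. All three builders are verified against independent
brute-force oracles (exhaustive pair enumeration, direct run scanning,
flood fill) on dozens of random phantoms, and against hand-computed
degenerate cases. One subtlety the oracle work surfaced: a two-level
parity checkerboard does *not* decompose into singleton zones under
26-connectivity, because equal-parity diagonal neighbors touch — it has
exactly two zones. The singleton-zone regime requires a pattern with no
equal-level contact at all, e.g. the 8-level parity pattern, which the
tests use for the ZLNU $= N_z$ case.

## Shape features

* **Elongation**: the ratio of the longest to the shortest edge of the
  bounding box aligned with the principal axes of the foreground
  voxel-center cloud (physical mm). The classical definition is 2-D (the
  minimum-area bounding rectangle of a region); we generalize to 3-D via
  the principal-axis box, which reduces to the 2-D reading in-plane and
  keeps the anchor that 1 means maximum symmetry. A 2-D variant on the
  largest axial slice is available (`mode = "slice2d"`). A single voxel
  gives 1 by convention; the value is always ≥ 1.
* **Sphericity**: $\pi^{1/3} (6V)^{2/3} / A = 1$ for a perfect sphere.
* **Compactness**: first-form compactness $V / (\sqrt{\pi} A^{3/2})$,
  scale-invariant, maximal ($1/6\pi$) for the sphere. No formula is
  standard under this name across software packages, so absolute values
  are not comparable between implementations.

$A$ and $V$ are the surface area and enclosed volume of a single closed
iso-surface mesh of the mask, built by marching tetrahedra at the 0.5
level: each cell of eight neighboring voxel centers is split into six
tetrahedra and the level-set crossing is triangulated with linear edge
interpolation. Two numerical choices matter here:

1. The binary field is pre-smoothed with a separable $[1,2,1]/4$ kernel.
   Meshing the raw 0/1 field leaves staircase facets that overestimate a
   sphere's area by roughly 30% (voxel-face counting: ~50%); the smoothed
   mesh brings a digital sphere's sphericity to ≈ 0.99. Voxels are
   classified "hot" strictly above 0.5 so the exact-tie values smoothing
   produces cannot create degenerate zero-thickness sheets, and masks thin
   enough that smoothing erodes most of their volume are re-meshed from
   the raw binary field.
2. $V$ is taken from the same mesh as $A$ (signed volume via the
   divergence theorem over consistently oriented triangles), not from the
   voxel count. With both measures on one closed surface the isoperimetric
   inequality applies exactly, so sphericity is guaranteed to lie in
   (0, 1] for every mask at every resolution — mixing voxel volume with
   mesh area can push coarse spheres above 1. MTV is unaffected (it stays
   voxel count × voxel volume).

## Response classification

`percist_classify()` applies the PERCIST-style rules to body-weight
SUVpeak with precedence PMD > CMR > PMR > SMD: PMD on a new lesion or an
increase ≥ 30% *and* ≥ 0.8 SUV; CMR when the post value is at or below the
background reference; PMR on a decrease ≥ 30% and ≥ 0.8 SUV; SMD
otherwise. The 30%/0.8 thresholds come from the published criteria. The
background reference is supplied by the caller/config — in the synthetic
study it is the background mean plus a two-sigma noise margin, as a
reference-region reading would give. `histologic_responder()` dichotomizes
the Salzer-Kuntschik grade: I–III (< 10% viable cells) responders, IV–VI
non-responders.

## Prognostic screening

Cox proportional-hazards fits use the partial likelihood with the Efron
correction for tied event times (`survival::coxph` behind the module
surface); hazard ratios are reported with Wald statistics and normal-based
95% intervals. Monotone-likelihood separation is surfaced as a flag plus a
warning, never a silently diverged coefficient. Design choices, each
configurable:

* Continuous features enter untransformed by default; median
  dichotomization is available (`dichotomize = TRUE`). Neither mode is
  claimed to match the original clinical analysis, which does not state
  its choice.
* The multivariate model includes only candidates whose univariate Wald p
  is ≤ `inclusion_alpha` (default 0.10, operationalizing "significant or
  nearly significant"); dropped candidates are reported as "not retained
  in model".
* p-values are not multiplicity-adjusted by default, mirroring the
  single-threshold reporting style of the clinical literature;
  `p.adjust`-style correction can be applied downstream on the returned
  table.

`spearman_delta_vs_grade()` rank-correlates a percent-change feature with
the regression grade (mid-ranks for ties, t-approximation p).
`detection_performance()` turns per-site detection counts into sensitivity
and specificity with exact Clopper–Pearson intervals, leaving
zero-denominator metrics explicitly undefined.

## The synthetic data generator

`generate_phantom()` renders an ellipsoidal FDG-avid lesion (voxel-center
membership test — the simplest unambiguous discretization, matching the
mask semantics downstream) on a uniform background, with a texture pattern
(uniform, gradient, checkerboard with configurable period — chosen because
it yields hand-computable texture matrices — or random Gaussian blobs) and
additive Gaussian noise clipped at zero (SUV is non-negative; realistic
PET noise models are out of scope). `generate_response_pair()` produces
the paired study: the post-therapy lesion's semi-axes shrink by
`volume_scale^(1/3)` and its uptake is scaled multiplicatively, floored at
the background level — treated tissue returns to background uptake, never
below it, so `uptake_scale = 0` yields a lesion indistinguishable from
background while any scale that keeps uptake above background changes
SUVmean by exactly `100 (uptake_scale − 1)` percent. The heterogeneity
pattern is drawn once per pair (both timepoints share it); only the noise
realization differs between scans.

`generate_cohort()` simulates survival: covariates from a configurable
model, event times from a Weibull proportional-hazards model
$T = \lambda(-\log U / e^{x^\top\beta})^{1/k}$ (default scale 1500 days,
shape 1.2 — median PFS on the order of three to four years, consistent
with pediatric sarcoma cohorts), overall survival as progression time plus
an independent post-progression Weibull, and independent uniform censoring
whose upper bound is calibrated by bisection to the target censoring
fraction (default 30%). The default covariate model — log-normal
elongation around 1.4 spanning roughly 1–3, Bernoulli lung (25%) and bone
(15%) metastasis flags, log-normal baseline SUVmax around 7 — is this
package's own choice of a plausible pediatric cohort; the clinical
literature publishes only summary tables, not distributions, so these
defaults are explicitly not presented as anyone's data. The histologic
grade distribution puts about one fifth of patients in the non-responder
grades.

`simulate_study()` ties the two together on disk: one phantom pair per
patient (the elongation covariate drives the lesion's long axis, linking
imaging to the survival model; responders draw larger uptake and volume
reductions), with 70% of patients receiving a post-chemotherapy scan — the
rest join only baseline analyses, as in real cohorts.

What the generator deliberately does **not** emulate: scanner point-spread
and reconstruction artifacts, attenuation and scatter, two-scanner
harmonization, respiratory motion, and non-ellipsoidal lesion geometry.
Green tests therefore demonstrate the correctness of the measurement
pipeline on known ground truth — not that the features are robust to
scanner physics, which requires real phantom acquisitions.

## Problem sizes and determinism

Every generator is bit-reproducible under a fixed seed, and a full
simulated study reruns byte-identically (the run manifest records
settings, seed and package version, and contains no timestamps). The test
suite exercises: texture oracles on 50 random 4×4×4 phantoms; SUVpeak
against brute-force enumeration on 20 phantoms; segmentation recovery on
three sphere radii at 4:1 contrast; Cox coverage and bias over 100
simulated cohorts of n = 400 at 30% censoring; and a 60-patient
end-to-end study on 28³ grids — sizes chosen to give each check real
statistical teeth while keeping the whole suite interactive.

## Known limitations

* Axis-aligned volumes only; no DICOM ingestion (convert to NIfTI first).
* One lesion per seed; no automatic multi-lesion detection.
* The adaptive-threshold parameters are a documented stand-in, not a
  reproduction of any clinical calibration.
* Elongation of a mask whose voxel centers are exactly coplanar is
  reported as `Inf` (the principal-axis box has a zero edge).
* Absolute compactness values are implementation-specific; compare only
  within one pipeline.
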