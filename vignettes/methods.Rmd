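---
title: "Methods: morphometry, quality assessment, BMD regression, and triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometry, quality assessment, BMD regression, and triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoscreen)
```

## The screening problem

Dual-energy X-ray absorptiometry (DXA) is the reference standard for
measuring areal bone mineral density (BMD, g/cm²) and diagnosing
osteoporosis (T-score ≤ −2.5), but it is widely under-used. Opportunistic
screening instead re-uses hip and lumbar-spine radiographs already acquired
for other indications: regions of interest (ROIs) around the hips or the
L1–L4 vertebral bodies are extracted from anatomical landmarks, checked for
conditions that invalidate densitometry (implants, fractures, collapsed
vertebrae), fed to a regressor that estimates BMD, and the resulting
T-scores routed through a dual-threshold triage that either classifies a
patient confidently or refers them for confirmatory DXA.

`osteoscreen` implements that screening pipeline as testable components, and
pairs it with a synthetic phantom/cohort generator so that every stage can
be exercised and validated without clinical images. Landmark detection and
the detection networks for implants and fractures are upstream, pluggable
inputs: the package consumes landmark coordinates and detector probability
maps, not raw radiographs.

## Six-point morphometry and the deformity criteria

Each vertebra is summarised by six landmarks — anterior, posterior, and
mid-plate point pairs on the superior and inferior endplates. From these,
`compute_morphometry()` derives the anterior, posterior, and middle heights
\(h_a, h_p, h_m\) (pairwise distances within each landmark pair) and the
width \(w\), taken as the mean of the superior-edge and inferior-edge
anterior–posterior distances. The published definition of the width says
only "mean distance between the anterior and posterior points"; the
symmetric reading used here (mean of the two same-plate distances) is the
only pairing that does not mix superior with inferior landmarks, which is
why the alternatives were rejected.

Three Genant-derived criteria flag moderate-to-severe deformity, each a
strict inequality:

* c1 (wedge/crush): \(\min(h_a,h_p)/\max(h_a,h_p) < 0.8\)
* c2 (biconcave): \(h_m/\max(h_a,h_p) < 0.6\)
* c3 (severe collapse): \(\max(h_a,h_p)/w < 0.55\)

A ratio exactly at its threshold does **not** fire; ties are classified
normal. The ratios are dimensionless, hence invariant under translation,
rotation, and uniform scaling of the landmarks — a property the test suite
verifies on random similarity transforms. Mild (Genant grade 1) deformity is
deliberately out of scope: the thresholds were chosen upstream to avoid
borderline calls, and this package does not attempt to grade below them.

When several criteria fire, `classify_deformity()` labels by severity:
c3 (severe) over c1 (wedge/crush) over c2 (biconcave). No precedence is
published for simultaneous flags; this ordering is a documented package
choice, made because c3 indicates global collapse which subsumes the other
two patterns.

Self-intersecting landmark hexagons are rejected with an error rather than
silently measured: a crossed outline means the landmark detector failed, and
any heights computed from it would be meaningless.

## Quality assessment

**Hip.** The fracture and implant detectors return probability maps aligned
to the image; the ROI score is the *maximum* response over grid cells whose
centres fall inside the ROI polygon (`aggregate_roi_score()`). Cell centres
exactly on the polygon boundary are included; this convention is pinned so
results are bit-reproducible. A hip ROI is excluded when either score
reaches its threshold, inclusively (score ≥ threshold). The operating
thresholds of the published detectors are not public; the default here is
0.5 per channel and both channels share it, configurable in
`pipeline_config()`.

**Spine.** Admissibility is decided in three ordered steps, and a vertebra
excluded at one step never contributes to later steps:

1. vertebrae with a positive implant or VCF detection are excluded;
2. survivors are measured by six-point morphometry and excluded if any of
   c1–c3 fires;
3. survivors' predicted T-scores pass through the neighbour-deviation rule.

If fewer than two vertebrae survive, the whole scan is inadmissible — the
standard minimum-vertebra convention for lumbar densitometry.

The neighbour-deviation rule excludes a vertebra whose T-score differs from
its peers by more than 1.0 T-score units (strict inequality; exactly 1.0 is
retained). The source description — "more than one standard deviation
difference from their neighbors" — is ambiguous about the reference. Two
readings are implemented. The default, `method = "loo"`, compares each
vertebra with the mean of all *other* assessable vertebrae: with a chain of
four values, comparing strictly against adjacent neighbours would also
discard the innocent neighbours of a single deviant vertebra (the deviant's
neighbour sees the same large pairwise difference), while the leave-one-out
mean isolates the outlier itself, which is the intent of the underlying
ISCD exclusion convention. `method = "adjacent"` (mean of chain-adjacent
vertebrae) is available for comparison. The margin `neighbor_delta` is
configurable; the decision is single-pass on the pre-exclusion values —
cascading re-evaluation could empty the set and no iteration rule is
published. Whether the rule should see predicted BMD or predicted T-scores
is likewise unstated upstream; T-scores are used because the 1.0 margin is
a T-score quantity.

## The reference BMD regressor

The published regressor is a GPU-trained convolutional network
(VGG-16/ResNet-34 backbone) trained on tens of thousands of clinical ROIs;
reproducing it is explicitly out of scope. What the package keeps is the
*training and inference contract*, at a scale a laptop CPU handles:

* preprocessing: resample to 0.15 mm/pixel, min–max normalise to [0, 1]
  (a constant image maps to 0.5), letterbox to a square model input
  (512×512 by default). Preprocessing is deterministic and idempotent.
* augmentation: random affine transforms (defaults ±10° rotation, ±5% scale
  and translation, no shear — no ranges are published; these are
  conventional mild ranges), sampled per-image from an explicit seed.
* a pluggable backbone encodes the grid as a feature vector. The bundled
  `intensity_backbone()` uses intensity summaries (mean, SD, quantiles,
  central-crop mean) — sufficient for the phantom family, whose density
  signal is an affine intensity shift, and honest about not being a
  texture-learning CNN. Any function `grid -> numeric` can replace it.
* for vertebral ROIs the L1–L4 level is appended as a one-hot vector of
  length 4 before the final read-out, mirroring the level-specific geometry
  and BMD statistics of the lumbar spine.
* training minimises an L1 (least-absolute-deviation) loss — smoothed with
  half-width `l1_eps` (default 0.001 g/cm², well below DXA precision) and
  optimised by a majorize–minimize reweighting scheme whose per-epoch loss
  is logged and non-increasing by construction.
* the data are split into four seeded folds of near-equal size; member *m*
  trains on the other three folds, and inference averages the four members.
  Predictions are floored at 0.05 g/cm² (flagged when clamping occurs). No
  member is ever rejected for disagreeing with the others; no rejection
  rule is published and the ensemble mean is the published combiner.

Age and sex are deliberately not model inputs (adding them did not improve
the published model); the backbone interface leaves room to experiment.

## Synthetic phantoms and cohorts

The generator's role is to make every downstream stage testable with known
ground truth, not to render realistic radiographs.

* **Landmarks.** `generate_vertebra_landmarks()` emits six points whose
  morphometry reproduces a requested deformity family by construction:
  wedge scales \(h_a\) by \(1-s\) (so r1 = 1−s and c1 fires exactly when
  severity exceeds 0.2), biconcave scales \(h_m\), crush scales both wall
  heights asymmetrically, severe_flat scales all heights (controlling r3).
  Severity 0 is bit-identical to the undeformed geometry.
* **Images.** A phantom ROI is a flat background (4000), a fixed
  calibration marker (62000) in one corner, and a central bone block whose
  intensity is affine in true BMD: \(10000 + 30000\,\mathrm{BMD}\). The
  affine map is the simplest strictly monotone choice with a closed-form
  noise-free mean (`phantom_mean_intensity()`), and the fixed-intensity
  marker guarantees that per-image min–max normalisation cannot erase the
  density signal. Noise is additive Gaussian on pixel intensities
  (default SD 500 ≈ 1% of full scale), clamped to the 16-bit range —
  a standard proxy for radiographic noise. Identical spec and seed give
  bit-identical images, and no call touches the global RNG state.
* **Cohorts.** `generate_cohort()` draws each patient's osteoporosis status
  as Bernoulli(prevalence) — defaults 0.215 (hip) and 0.433 (spine),
  matching large opportunistic screening cohorts — places the lowest
  T-score accordingly (osteoporotic in (−4.5, −2.5], otherwise in
  (−2.5, 1.5)), assigns one ROI exactly at the lowest T with the others
  above it, and converts T to BMD through the reference table. DXA
  measurement error is Gaussian with SD 0.01 g/cm² — a stated assumption at
  densitometer precision level, since no repeatability figure is published
  for the source cohorts. Ages are uniform on [40, 90] (the inclusion
  window), the female fraction is 0.78, and radiograph–DXA gaps are
  exponential with the cohort medians (29/16 days), capped at 180.

What the phantoms deliberately do **not** model: bone texture,
osteophytes, soft tissue, bowel gas, projection geometry, or any feature a
CNN would exploit on real radiographs. Consequently, passing tests
demonstrate that the pipeline's logic, contracts, and statistics are
correct — not that any particular backbone would reach clinical accuracy.
The published clinical performance (hip correlation 0.92, AUROC 0.97, …)
requires the clinical cohorts and trained weights and is not an acceptance
surface for this package.

## T-scores, reference values, and triage

T-scores are `(BMD − young-adult mean)/SD`. The young-adult references are
configuration, not bundled clinical constants, with one exception worth
explaining: the default *hip* entry (mean 0.83683, SD 0.11167 g/cm²) is
derived from the internal consistency of the published dual-form hip triage
thresholds, which are printed both as BMD and as T-scores
(0.513 g/cm² ↔ −2.9 and 0.580 g/cm² ↔ −2.3). Those two equations determine
the implied reference exactly, and using it makes the package's BMD-scale
and T-score-scale triage agree with both printed forms. The spine
references (printed only as T-scores upstream) are synthetic per-level
defaults consistent with typical Hologic lumbar reference ranges; replace
them for any real deployment.

Classification is inclusive at every published cut-off: osteoporosis at
T ≤ −2.5, high 10-year major-osteoporotic-fracture risk at ≥ 20%, high hip
fracture risk at ≥ 3%. The bundled `toy_risk_model()` is a documented
logistic toy for exercising this plumbing — it is **not** FRAX, which is an
external proprietary calculator; any `(age, sex, lowest_t)` function can be
plugged in. Device cross-calibration (`convert_device()`) is a configurable
affine map with identity default, since manufacturer conversion
coefficients are not published.

Triage routes a value \(v\) (BMD or T-score — one scale per cohort, never
mixed) through `t1 < t2`: \(v < t_1\) classified osteoporotic,
\(t_1 \le v < t_2\) referred for DXA, \(v \ge t_2\) classified
non-osteoporotic. The half-open middle interval matches the published
categorisation rows. `find_threshold()` searches these operating points on
data: the largest `t1` whose below-threshold calls reach the target PPV
(capturing as many positives as the constraint allows), and the smallest
`t2` whose at-or-above calls reach the target NPV; candidates are the
distinct observed values plus the open extremes, and an unattainable target
returns an explicit no-solution result.

## Evaluation statistics

* Agreement: Pearson correlation; R² and RMSE from the OLS regression of
  measured on predicted. The regression direction is not stated upstream;
  measured-on-predicted is chosen because it makes slope ≈ 1 and
  calibration-in-the-large ≈ 0 the ideal, consistent with the published
  hip values (slope 0.982, CITL −0.003, bias −0.003).
* Calibration-in-the-large is `mean(measured) − mean(predicted)` — with
  this sign convention it is *identically* the Bland–Altman bias
  (differences measured − predicted; sample SD with n−1), an identity the
  tests assert on random samples.
* Discrimination: AUROC as the midrank Mann–Whitney statistic (equal to the
  trapezoidal area over distinct thresholds), AUPRC as step-wise average
  precision — not trapezoidal PR interpolation, which differs and would
  overstate it. Orientation is documented: lower predicted BMD/T means more
  osteoporotic, so callers pass negated values as scores.
* Confusion metrics: the standard rates with Wilson 95% intervals, and an
  odds ratio with a Woolf log-method CI, adding 0.5 to every cell when any
  cell is zero. Neither the CI method for the rates nor for the OR is
  stated upstream; Wilson and Woolf are the conventional choices and are
  documented rather than asserted against published intervals.
* Table-style percentages round half-up to one decimal, matching clinical
  report conventions (base R `round()` would round half-even).

## Numerical and scale choices

Problem sizes in the tests and the acceptance script are chosen for a
single CPU: the morphometry property suite uses 1000 random landmark sets,
the ROI-aggregation oracle 500 random map/polygon pairs, and the
phantom-recovery experiment 400 phantoms (64 px) with 256 px model inputs,
20 training epochs, and one augmented copy per image — the four-fold
ensemble then recovers held-out true BMD with Pearson r ≥ 0.9, the
synthetic analogue (not a reproduction) of the clinical correlation claim.
Image resampling uses bilinear interpolation with 0-based pixel centres;
border samples replicate the edge during resampling, while augmentation
fills outside samples with zero. All randomness flows from explicit seeds —
fold assignment, augmentation draws, phantom noise, and cohort sampling are
reproducible bit-for-bit, and generators restore the caller's RNG state.

## Known limitations

* The phantom image family is deliberately simple; a learned backbone's
  clinical accuracy cannot be established here.
* The spine reference table and all detector thresholds are synthetic or
  default configuration values, not published constants.
* The bundled risk model is a labelled toy; FRAX integration is an
  interface, not an implementation.
* Mild vertebral deformity is not graded, by design.
* Neighbour-deviation exclusion supports two documented readings of an
  ambiguous rule; results can differ between them on pathological chains.
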