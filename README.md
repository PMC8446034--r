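# osteoscreen

Opportunistic osteoporosis screening from hip and lumbar-spine radiograph
regions of interest (ROIs), for researchers building or validating
automated bone-density pipelines.

Dual-energy X-ray absorptiometry (DXA) — the reference standard for areal
bone mineral density (BMD, g/cm²) — is chronically under-used, so most
at-risk patients are never screened. Opportunistic screening re-uses
radiographs already acquired for other indications: ROIs around the hips or
the L1–L4 vertebrae are quality-checked, a regressor estimates BMD, the
estimate becomes a T-score, and a dual-threshold rule either classifies the
patient confidently or refers them for confirmatory DXA. `osteoscreen`
implements that pipeline as tested, composable parts, together with a
synthetic phantom and cohort generator so every stage runs without clinical
data.

## What's inside

* **Six-point vertebral morphometry** — heights `h_a`, `h_p`, `h_m` and
  width `w` from the six endplate landmarks, and the three Genant-modified
  deformity criteria (strict inequalities):

  ```
  min(h_a, h_p) / max(h_a, h_p) < 0.80   (wedge / crush)
  h_m / max(h_a, h_p)           < 0.60   (biconcave)
  max(h_a, h_p) / w             < 0.55   (severe collapse)
  ```

* **Radiograph quality assessment** — maximum detector response over the
  ROI polygon as the classification score; hip fracture/implant exclusion;
  the three-step spine procedure (implant/VCF detection → morphometry →
  neighbour-deviation rule) with the two-assessable-vertebrae minimum.
* **A pluggable BMD regressor** — the standard training contract
  (resample to 0.15 mm, affine augmentation, L1 loss, one-hot vertebral
  level, seeded four-fold ensemble averaged at inference) around a
  swappable backbone, with a reference intensity-feature backbone that
  trains in seconds on phantoms.
* **T-scores, risk, triage** — `T = (BMD − ref_mean)/ref_sd`, osteoporosis
  at `T ≤ −2.5`, high 10-year risk at ≥ 20 % (major) / ≥ 3 % (hip), device
  cross-calibration, and dual-threshold triage
  (`v < T1` → osteoporotic, `T1 ≤ v < T2` → refer DXA, `v ≥ T2` →
  non-osteoporotic).
* **Evaluation statistics** — Pearson r, R²/RMSE, calibration slope and
  calibration-in-the-large, Bland–Altman, AUROC/AUPRC,
  sensitivity/specificity/PPV/NPV with Wilson intervals, odds ratios, and
  the 95 %-PPV/NPV threshold search.
* **Synthetic data** — deformable vertebra landmark sets, 16-bit phantom
  ROI images with a documented affine intensity–density map, and paired
  radiograph/DXA cohorts with controllable prevalence.

## Worked example

Morphometry of a synthetic wedge-deformed vertebra (35 % anterior height
loss), then a small end-to-end hip screening run:

```r
library(osteoscreen)

spec <- phantom_spec(true_bmd = 0.62, deformity = "wedge", severity = 0.35, seed = 7)
lm1  <- generate_vertebra_landmarks(spec, base_height = 25, base_width = 35, level = "L2")
compute_morphometry(lm1)
#> Vertebral morphometry (L2)
#>   heights (mm): anterior 16.25, posterior 25.00, middle 20.62; width 35.54
#>   ratios: r1 = 0.650 (c1 FIRES), r2 = 0.825 (c2 ok), r3 = 0.703 (c3 ok)
#>   ABNORMAL: wedge_or_crush
```

The anterior/posterior ratio 0.650 breaches the 0.80 wedge criterion, so
this vertebra would be excluded from BMD estimation.

```r
cfg      <- pipeline_config(site = "hip", n_patients = 30, seed = 21,
                            roi_size = 48, bmd = bmd_config(input_size = 96, epochs = 15))
study    <- simulate_study(cfg)        # cohort + phantom ROIs with known truth
ensemble <- run_train(cfg)             # reference 4-fold ensemble on phantoms
report   <- run_screen(study, ensemble)
report
#> Screening report: 30 patients (30 ok, 0 inadmissible, 0 error)
#>   classified_osteoporotic      6
#>   refer_dxa                    2
#>   classified_non_osteoporotic  22

m <- run_evaluate(cfg, study, report)
#> pearson r 0.997 | slope 0.998 | CITL -0.020 | AUROC 1.000
```

All 30 patients pass QA and reach a triage category; the predicted lowest
T-scores track the simulated truth almost perfectly because the phantom
intensity–density map is affine by design (see the methods vignette for
what that does and does not demonstrate).

Confusion-table metrics recompute published-style screening tables from raw
counts:

```r
confusion_metrics(tp = 524, fp = 25, tn = 3812, fn = 196)
#> Confusion table: TP 524, FP 25, TN 3812, FN 196
#>   accuracy     95.2% (95% CI 94.5-95.7)
#>   sensitivity  72.8% (95% CI 69.4-75.9)
#>   specificity  99.3% (95% CI 99.0-99.6)
#>   ppv          95.4% (95% CI 93.4-96.9)
#>   npv          95.1% (95% CI 94.4-95.7)
#>   OR 407.65 (95% CI 266.20-624.26)
```

A thin CLI over the same functions lives at `inst/cli/osteoscreen.R`
(subcommands `simulate`, `screen`, `evaluate`, configured by a
schema-validated YAML file).

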