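# cusweep

Standard-view extraction and severity screening logic for neonatal cranial
ultrasound (CUS) sweep videos.

Screening high-risk neonates for severe cerebral lesions — grade III/IV
intraventricular hemorrhage (IVH), periventricular leukomalacia (PVL),
hydrocephalus — relies on cranial ultrasound sweeps through the anterior
fontanelle, from which a trained reader extracts six canonical standard
views and grades the findings. `cusweep` re-implements the *decision
layer* of an automated screening system for this task, for researchers who
want to study, stress-test or re-parameterise that logic without the
neural perception components: the package consumes per-frame rotated-box
detection streams and per-image lesion probabilities, not pixels.

What it does:

* **View extraction.** Every frame is scored as
  `Score = Σ base_score(structure) × confidence` over its detections;
  frames meeting a view's anatomical criteria enter that view's candidate
  queue; per-view DBSCAN clustering of (frame index, score) points infers
  the sweep direction (coronal AHV→TVV→BV, sagittal LPSV→MSV→RPSV, or the
  reverse), rejects noise and out-of-order clusters with an audit trail,
  and selects the highest-score candidate per view — or reports the view
  absent.
* **Severity diagnosis.** Per-image multi-label probabilities over
  {normal, IVH, ependymal cyst, ventricular dilation, hydrocephalus, PVL}
  are thresholded and combined with a case-level binary head by the
  ensemble rule
  `severe = binary_severe OR (multilabel_severe AND abnormal_count ≥ 2)`,
  where the multi-label route fires when one image shows PVL,
  hydrocephalus, or IVH together with ventricular dilation. Ground-truth
  severity follows the Papile-based convention.
* **Evaluation.** Sensitivity/specificity/PPV/NPV/F1, trapezoidal ROC AUC,
  Clopper–Pearson and bootstrap CIs, and rotated-box mean average
  precision with exact polygon-clipping IoU.
* **Reader-trial statistics.** Bang's blinding index with bootstrap CI,
  Cohen's and Fleiss' kappa, two-proportion differences (Wald/Newcombe,
  Pearson chi-square), one-sided Welch t, exact-small-sample Wilcoxon
  signed-rank, Benjamini–Hochberg.
* **Synthetic data.** Seeded generators of sweep detection streams
  (Gaussian visibility bumps, jitter, dropout, spurious detections) and
  diagnostic cohorts with known ground truth, so the whole pipeline is
  testable offline.

## Worked example

```r
library(cusweep)

# a seeded coronal sweep with planted standard views at frames 30/60/90
sim <- simulate_sweep(sweep_spec(plane = "coronal", seed = 7))
sim$truth$peaks
#> AHV TVV  BV
#>  30  60  90

extract_views(sim$stream)
#> <extraction_result direction=forward views=3/6 dropped=14>
#>   AHV: frame 30
#>   TVV: frame 60
#>   BV: frame 90
```

All three planted views are recovered exactly and the sweep is recognised
as a forward (anterior-to-posterior) scan; 14 low-density tail candidates
were dropped as noise, each recorded with its reason in `$dropped`. The
diagnostic stage on a simulated grade-III IVH case:

```r
case <- simulate_cohort(cohort_spec(n_cases = 1, prevalence = c(IVH_III = 1),
                                    seed = 8))[[1]]
ensemble_decision(case$input)
#> <case_decision severe=TRUE (binary head predicted severe)>
```

The metrics layer reproduces screening arithmetic directly from confusion
counts — here the blind-sweep evaluation of the published system (8 severe
and 103 non-severe diagnosable cases):

```r
binary_metrics(confusion_counts(tp = 8, fn = 0, fp = 4, tn = 99))
#> sensitivity specificity         ppv         npv          f1
#>   1.0000000   0.9611650   0.6666667   1.0000000   0.8000000

d <- two_proportion_diff(42, 757, 158, 762)   # blinded-trial outcome arms
#> diff -15.2% (95% CI -18.5% to -11.9%), chi2 = 76.6, p = 2.1e-18
```

A thin command-line surface (`inst/cli/cusweep.R`) exposes
`simulate-sweep`, `simulate-cohort`, `extract`, `diagnose`, `evaluate`,
`trial-stats` and `ap-eval` over JSONL/CSV/YAML files; see the script
header for usage.

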