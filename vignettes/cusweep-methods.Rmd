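---
title: "Screening cranial ultrasound sweeps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cranial ultrasound sweeps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cusweep)
```

## The screening problem

Neonatal cerebral lesions — intraventricular hemorrhage (IVH), cystic
periventricular white-matter injury (PVL), hydrocephalus, ventricular
dilation — are screened with cranial ultrasound through the anterior
fontanelle. A full examination sweeps the probe across the fontanelle in
the coronal and the sagittal orientation; a reader then picks out six
canonical standard views (anterior horn, third ventricle and
lateral-ventricle body views in the coronal sweep; midsagittal and the two
parasagittal views in the sagittal sweep) and grades what they show. By the
Papile convention, grade III/IV IVH, PVL and hydrocephalus are *severe*
findings warranting intervention; grade I/II IVH, ependymal cysts and
minor ventricular dilation are mild.

`cusweep` implements the decision logic of such a screening system in a
perception-agnostic way. It deliberately starts *after* the neural
perception components: the input is the per-frame output of a rotated-box
anatomical-structure detector (a detection stream), and per-image lesion
probabilities plus a case-level severity probability from a classifier.
Everything downstream of those — candidate-frame scoring, sweep-direction
inference, standard-view selection, the rule-based severity ensemble, the
evaluation metrics and the reader-trial statistics — is ordinary,
testable code, exercised end to end on synthetic data with known ground
truth.

## Stage 1 — standard-view extraction

### Frame scoring

Each frame of a sweep reduces to a set of detections
(structure label, confidence, rotated box). A frame's score is

$$\mathrm{Score} = \sum_{\text{detections}} \text{base score}(\text{structure}) \times \text{confidence},$$

summed over detections at or above `detector_conf_floor` (default 0.5, a
standard detector operating point). Base scores weight view-defining
structures; only their ordering matters, and uniformly rescaling all base
scores provably changes neither selection nor direction (a tested
invariant).

A frame enters the *candidate queue* of view V when every structure V
requires is detected at confidence at least V's `min_confidence` (closed
threshold, default 0.5) and no structure V forbids is present. The shipped
criteria follow the usual sonographic definitions: paired anterior horns
for AHV, the third ventricle for TVV, lateral-ventricle body plus choroid
plexus for BV, corpus callosum plus cerebellar vermis for MSV, and the
side-specific lateral ventricle plus thalamus for the parasagittal views.
The exact base-score values carry no published reference; they are
configuration, not constants, and every number can be overridden in a YAML
run configuration (`read_run_config()`).

### Direction inference and filtering

Candidates of each view are embedded as (frame index, score) points, each
axis min-max normalized to [0, 1] over all candidates of the stream, and
clustered per view with DBSCAN (`eps = 0.1`, `min_samples = 3` by
default). The highest-total-score cluster of a view defines its centroid
frame; the sweep direction is `forward` when centroids follow the
anatomical order (coronal: AHV → TVV → BV, anterior to posterior;
sagittal: LPSV → MSV → RPSV, left to right), `reverse` for the exact
mirror, `unknown` otherwise. Two design points deserve note:

* **Per-view clustering.** Clustering could be run jointly over all
  candidates; we cluster per view, which keeps a view's tail frames from
  bridging into a neighbouring view's cluster. The choice is isolated in
  `cluster_candidates()` and easy to revisit.
* **DBSCAN determinism.** Classic DBSCAN leaves border-point assignment
  order-dependent. Our implementation resolves it deterministically and
  order-independently: a border point joins the cluster of its nearest
  core neighbour, ties toward the lowest point index. The test suite
  checks equality against a brute-force density-reachability closure on
  hundreds of random instances.

Filtering then removes, with an audit trail: candidates labelled noise
(reason `"noise"`), and — when the direction is known — whole clusters
whose centroid falls behind the last accepted cluster when views are
visited in the direction's order (reason `"order"`). An unknown direction
disables only the order filter, never the noise filter: the system fails
toward still returning some view. Dropped plus surviving candidates always
equal assigned candidates (tested invariant).

Finally `select_standard_views()` picks the maximum-score surviving
candidate per view, ties toward the earliest frame; an empty queue reports
the view as absent rather than guessing.

## Stage 2 — ensemble severity diagnosis

Per-image multi-label probabilities over
{normal, IVH, ependymal cyst, ventricular dilation, hydrocephalus, PVL}
are thresholded at `tau` (default 0.5, closed). The decision logic is:

* an image is **abnormal** when it is not exclusively normal, i.e. some
  non-normal label is positive. An image with *no* positive label is
  treated as carrying no abnormal evidence (not abnormal) — a literal
  reading could call it "not exclusively normal", but counting silence as
  pathology would inflate the abnormal count with uninformative images;
* the **multi-label rule** calls a case severe when a single image shows
  PVL, hydrocephalus, or IVH co-occurring with ventricular dilation *on
  that same image* (IVH on one view and dilation on another does not
  qualify — the co-occurrence is what distinguishes high-grade IVH);
* the **ensemble**:
  `severe = binary_severe OR (multilabel_severe AND abnormal_count >= 2)`,
  where `binary_severe` is the case-level probability thresholded at
  `tau`. The binary head can call severe on its own; the multi-label route
  additionally demands corroboration on at least two images.

All eight combinations of (binary, multi-label, count ≥ 2) are tested
exhaustively, as is monotonicity: raising any abnormal-label probability
can never revoke a severe call. Ground-truth conditions map to labels via
the Papile-based convention in `papile_case_label()`. The operating point
of the binary head is not published; 0.5 is the package default and a
`run_config()` knob. "Ventriculomegaly" in the severe rule is identified
with the `ventricular_dilation` label, the only dilation label in the
six-label vocabulary. A case with fewer than `min_views` (default 3)
extracted standard views is reported *not diagnosable* instead of being
forced through the ensemble.

## Metrics and trial statistics

The evaluation layer implements the standard screening metrics
(sensitivity, specificity, PPV, NPV, F1) with zero-denominator cases
signalled per metric; ROC AUC by trapezoid over unique thresholds, which
equals the Mann–Whitney pair-count statistic with half-credit ties
(both routes tested against each other and against an established ROC
implementation); exact Clopper–Pearson intervals from Beta quantiles; and
a seeded percentile bootstrap for metrics without a closed-form interval.
Rotated-box detection quality is summarised by per-class average precision
with all-point interpolation and greedy per-frame confidence-ordered
matching; the IoU of rotated boxes is computed exactly by
Sutherland–Hodgman clipping plus the shoelace formula, verified against a
Monte-Carlo area-sampling oracle. The mAP IoU threshold defaults to 0.5
and is exposed, as no published value exists for this system.

Reader-trial statistics: Bang's arm-wise blinding index
$(\text{correct} - \text{incorrect})/n$ with don't-know answers in the
denominator and a seeded trinomial bootstrap CI (the published CI
procedure is not specified; 2000 replicates by default); Cohen's and
Fleiss' kappa; two-proportion differences with Wald intervals (Newcombe
behind a flag) and Pearson chi-square without continuity correction;
one-sided Welch t; a paired Wilcoxon signed-rank test with exact
enumeration up to 12 nonzero differences (valid under ties, unlike the
textbook exact tables) and a tie-corrected normal approximation beyond;
and Benjamini–Hochberg adjustment. Wald was chosen for the difference CIs
because it reproduces the published trial table to printed precision; the
second row's printed lower bound matches neither Wald nor Newcombe
exactly, and no agreement is forced.

## The synthetic-data model

`simulate_sweep()` emulates the one feature of a sweep video the
extraction logic actually consumes: structure confidences that rise and
fall as the probe crosses each standard plane. Per view and required
structure, confidence follows a Gaussian bump
$c(t) = 0.9\,e^{-(t - t_v)^2 / (2\sigma^2)}$ centred on the planted frame
$t_v$, with $\sigma = 8$ frames — each plane stays visible for roughly 30
frames, about a second of video, as in a slow screening sweep. Gaussian
confidence jitter (sd 0.05), detection dropout (probability 0.1) and
Poisson spurious detections (0.2 per frame) model detector noise; spurious
confidences are drawn from a right-skewed Beta(1.5, 5), since a usable
detector's false positives are predominantly low-confidence — uniform
false-positive confidences would describe a detector no screening system
could sit on. Detections below 0.05 are not emitted (the detector's
emission floor). Everything is seeded and byte-reproducible.

`simulate_cohort()` draws ground-truth conditions from a prevalence vector
(default: 55% normal, severe rate 0.17, the remainder spread over mild
findings as in a high-risk screening population), plants per-image
probability profiles (severe-defining labels at mean ≥ 0.85, absent labels
at 0.05, noise sd 0.05) on at least two lesion-bearing images per abnormal
case, and draws the binary-head probability around 0.85/0.15 for
severe/non-severe cases.

What the generator does *not* model: pixel content, speckle, probe
pressure and fan geometry, correlated frame-to-frame detector errors,
classifier miscalibration, and lesions visible on exactly one view.
Passing the synthetic recovery and cohort-accuracy suites therefore shows
that the *decision logic* is correct under its stated assumptions — it
says nothing about any particular detector's or classifier's clinical
performance.

## Problem sizes and numerical conventions

The test and acceptance workloads use 100 seeded 120-frame sweeps
(recovery within ±3 frames ≥ 95%, direction accuracy ≥ 95%), a 200-case
cohort (sensitivity and specificity ≥ 0.95 under well-separated profiles),
200 random DBSCAN instances (n ≤ 60) against the brute-force oracle, 100
Monte-Carlo IoU checks at $10^5$ samples, and exhaustive sign-flip
enumeration for the Wilcoxon test up to n = 10. Conventions: frames are
0-based; angles are degrees in the half-open interval [−90, 90), reduced
in 90° steps with width/height swaps so normalization is idempotent;
probability thresholds are closed (≥); selection ties break to the
earliest frame; cluster-total ties break to the lower cluster label; all
randomness flows through explicit seeds and restores the caller's RNG
state.

## Known limitations

* The anatomical base scores and candidate criteria are plausible defaults,
  not published values; results on real streams will depend on them.
* The order filter trusts the direction inferred from the primary
  clusters; a sweep that genuinely reverses mid-video violates the model
  and will be filtered toward whichever ordering dominates.
* The severity ensemble is binary (intervention vs not); it does not name
  specific conditions.
* Published sensitivity-style confidence intervals for the original
  system match neither Clopper–Pearson nor Wald for any plausible integer
  counts; both methods are provided, and neither is claimed to reproduce
  those published cells.
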