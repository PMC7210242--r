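---
title: "Methods: simulating and calibrating fluorescence-guided margin assessment"
author: "fluorMargin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and calibrating fluorescence-guided margin assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorMargin)
```

## The problem

In breast-conserving surgery, residual tumor at the edge of the excision
cavity ("positive margins") sends roughly a fifth of patients back for a
second operation. Intraoperative fluorescence imaging with a
protease-activated probe offers a way to inspect the cavity walls during
the first procedure: cathepsin activity around tumor cleaves the probe and
produces far-red signal that can be imaged with a handheld device covering a
2.6-cm circular field of view per placement.

The analysis behind such a device has several coupled stages, each with its
own failure modes: the probe needs time to activate after intravenous
injection; the probe must actually touch the cavity wall; fluorescence must
be normalized per patient, because baseline (normal-tissue) signal varies
between patients; a detection threshold must be chosen; device readings per
margin orientation must be adjudicated against histopathology, which has its
own margin-status rules. `fluorMargin` implements this pipeline end to end,
together with a synthetic image generator that provides ground truth, so
every stage can be tested quantitatively.

## The signal model

A rendered field of view is a square pixel grid holding the inscribed
circular field. Pixels outside the circle are invalid and carried as `NA`
(never zero, so they cannot bias any statistic). The in-field signal is

$$ S(x) \;=\; A(t)\; c\; B_p\; \bigl[\,1 + (R_{\mathrm{eff}}-1)\,K(x)\,\bigr]\;\bigl(1+\varepsilon(x)\bigr) $$

with the following ingredients.

* $B_p$ -- the patient's latent normal-tissue baseline, in arbitrary
  fluorescence units (AFU). No absolute fluorescence scale is reported for
  this class of device, so the AFU scale is arbitrary by necessity; every
  downstream quantity is a ratio. Baselines are drawn lognormally across
  patients (default mean 100 AFU, CV 0.2).
* $A(t) = t/(t + h)$ -- a phenomenological saturating activation curve in
  the injection-to-imaging interval $t$ (minutes), scaled to 1 at plateau.
  The default halftime $h = 5$ min puts $A(101) \ge 0.95$: by the earliest
  eligible imaging timepoint (101 min) activation has plateaued. The curve
  shape is a modelling choice; only the plateau behaviour beyond ~100 min is
  empirically anchored.
* $c \in (0,1]$ -- the probe--tissue contact factor. Well-seated fields draw
  $c \sim U(0.90, 1)$; contact failures (default rate 1.5%) draw
  $c \sim U(0.45, 0.80)$ and are meant to be caught by QC.
* $K(x)$ -- the tumor profile: a disc indicator convolved with a Gaussian
  kernel ($\sigma$ defaults to 1/42 of the grid side, ~0.6 mm at field
  scale), combined with the indicator by pixelwise maximum. Inside the tumor
  the relative signal is exactly $R_{\mathrm{eff}}$; outside the border it
  decays smoothly -- the halo produced by protease activity extending beyond
  the tumor margin. The ground-truth mask stores the indicator *before*
  convolution: halo is signal, not tumor.
* $R$ -- the tumor-to-normal (T:N) signal ratio, drawn per tumor as
  $N(3.9, 0.084)$ (truncated below at 1.5) so that means over specimens fall
  in the reported 3.78--4.11 band. $R_{\mathrm{eff}} = 1 + (R-1)e$ with an
  exposure factor $e$ described below.
* $\varepsilon$ -- multiplicative lognormal pixel noise with unit mean
  (default CV 0.1). The noise model is a modelling choice; nothing in the
  source data constrains it.

The ex-vivo reference signal stored on each field is the mean in-field
signal at full contact without noise, which makes the measured contact
score (mean in-vivo signal / ex-vivo reference) an almost unbiased estimate
of $c$.

### What makes the problem hard: hotspots and occult tumor

Two generator features create the realistic failure modes:

* **Benign hotspots** (default: 70% of surfaces carry one) are small,
  halo-free foci with relative intensity $U(1.6, 5.2)$. They emulate benign
  tissues with elevated fluorescence -- the dominant false-positive source.
  Most hotspots stay below the calibrated threshold; the minority that cross
  it produce the ~25--30% false-positive rate the operating point implies.
* **Occult tumor** (default: 15% of tumor-bearing surfaces) exposes only a
  fraction $e \sim U(0.05, 0.7)$ of its signal at the imaged wall,
  emulating tumor beneath the surface or thin disease below detectability.
  These produce sub-threshold tumor readings -- the false-negative source
  (3 of 17 tumor surfaces read below threshold in the motivating cohort).

The rates and intensity ranges were fixed once, by a small design study, so
that the leave-one-patient-out operating point of the full pipeline on
default-condition cohorts sits near 84% sensitivity / 73% specificity --
the operating point the clinical development cohort reported. This is a
calibration-consistency property of the simulator, not a reproduction of
clinical data: the test suite checks it within ±10 percentage points.

## Quality control

Two filters run before any calibration, in a fixed order (patients first,
then images):

* **Timepoint**: intervals below 101 min are excluded (the empirical lower
  bound; intervals of 56 and 92 min were the two observed violations). No
  upper cutoff is enforced -- 402 min is the longest observed interval and
  signal remained acceptable there.
* **Contact**: images with contact score $\le 0.84$ are excluded. The
  inclusive form of the rule is used, with a $10^{-9}$ floating-point slack
  so a measured ratio of exactly 0.84 is excluded regardless of binary
  representation. The summary statistic entering the score is the mean
  in-field pixel value; the source material does not pin this down, and the
  mean matches the interpretation of the ex-vivo specimen carrying "all or
  part of the total tissue signal".

Patient-level exclusion reasons mirror the enrollment accounting of the
motivating study (`enrollmentScenario()` reproduces its 45 − 5 = 40
bookkeeping): short interval, missed dose, necrosis/hematoma, lost data.
The filters are idempotent and monotone in the contact cutoff; both
properties are tested.

## Calibration

* **Baseline**: the median of all valid in-field pixels pooled over the
  patient's initialisation-scan images (3 tumor-free fields by default).
  The median rather than the mean keeps occasional benign foci from
  inflating the baseline.
* **Training samples**: one per margin surface -- the maximum normalized
  in-field pixel after exact 3×3 median smoothing, over all the surface's
  fields, labelled by ground-truth tumor presence. The sample unit (pixel,
  image, or margin) is not specified in the source material; the per-surface
  maximum matches how readings are used clinically (any area of signal above
  threshold makes the margin positive).
* **ROC**: candidate coefficients are the sorted unique sample values; the
  decision rule is strictly `value > coefficient`. Sensitivity and
  specificity are computed at the sample level; an exhaustive brute-force
  confusion-matrix oracle verifies every point in the tests.
* **Operating point**: the coefficient maximizing Youden's
  $J = \mathrm{sens} + \mathrm{spec} - 1$, ties broken toward the smaller
  coefficient (higher sensitivity). "Optimized both sensitivity and
  specificity" names no criterion; Youden's J is the standard symmetric
  choice, and the coefficient is exposed in the configuration so any other
  operating point can be imposed.
* **Per-patient thresholds**: `threshold[p] = coefficient * baseline[p]`.
  Everything downstream is scale-equivariant: multiplying a patient's pixels
  and baseline by any constant changes nothing (tested).

Because the original development cohort both tuned and re-applied its final
algorithm to the same data, `evaluateCohort()` reports either
*resubstitution* (the historical procedure) or *leave-one-patient-out*
estimates, clearly labelled; the held-out mode refits the coefficient
without the evaluated patient's surfaces.

When a cohort contains no tumor-bearing surface at all, there is nothing to
calibrate against: the pipeline then falls back to a conservative threshold
just above the largest observed normal signal and reports sensitivity as
undefined (`NA`), never silently 0 or 1.

## Detection

A field is classified by: exact 3×3 median smoothing (replicate-padded;
invalid pixels are excluded and restored as `NA`), strict comparison
`smoothed > threshold`, 8-connected component labelling, and a minimum
component area. The clinical rule is "any area of signal above threshold";
the 9-pixel default area is a speckle guard, an assumption of this package,
and is configuration-exposed. It is calibrated to the default 256-px grid
(9 px ≈ a 1-mm speckle); at other resolutions the guard should be scaled
with pixel area -- the test suite uses 2 px on its 48-px grids. The
highlight mask keeps exactly the retained components, and the display
overlay paints exactly those pixels red over the grayscale rendering (the
red-pixel count equals the retained suprathreshold area, tested).

Both the median filter and the component labelling are implemented in the
package: the detection rule needs an exact (unquantized) median over
arbitrary dynamic range and 8-connectivity, and is verified against direct
oracles in the tests. A margin orientation combining several fields is
positive if any field is positive.

## Adjudication

Histopathology margin status follows the clinical rules: invasive cancers
(IDC, ILC, mixed invasive) are positive when tumor is on ink; pure DCIS is
positive when it lies strictly within 2 mm of ink (exactly 2.0 mm is
negative -- the strict inequality as printed); mixed invasive + DCIS
findings are positive when either component rule fires; benign findings are
negative.

Device readings are adjudicated with shave-first arbitration: if a shaved
specimen was taken at the imaged site, the site's ground truth is "tumor
found anywhere in the shave" -- note this is deliberately distinct from
margin status, so a shave with IDC more than 2 mm from ink still counts as
a true positive. Only when no specimen was taken does the margin status of
the main specimen's outer surface decide.

The clinical-outcome logic for positive final margins: additional tissue
excised intraoperatively at the site of signal spares the patient a second
surgery; a device-positive site left unexcised requires reoperation; a
device-negative reading with benign re-excision histology is a correct
prediction that no tumor remained.

### Known tensions in the printed accounting

The printed materials do not fully reconcile: the narrative places all
three sub-threshold tumor images on intermediate surfaces, while the
final-margin table shows two device-negative rows (both with benign
re-excisions, so they do not contradict the 100% final-margin sensitivity
for *residual tumor*); and 14/17 is 82.4%, not the printed 84%. The package
reports counts computed from its own rules and documents, rather than
resolves, these tensions; per-image and per-margin accounting are both
available from the assessment table.

## Evaluation

`performanceSummary()` computes sensitivity TP/(TP+FN) and specificity
TN/(TN+FP) overall and per stage in exact arithmetic; undefined rates are
`NA`. `estimateTnRatio()` averages per-specimen tumor/normal mean-signal
ratios on transected-specimen renders; the normal region is defined as the
exact zero-set of the halo profile, so noise-free recovery of the drawn
ratio is exact to machine precision (tested). `concordanceReport()`
recomputes every desk-checkable quantity of the clinical accounting from
the packaged fixture tables and the package's own rules.

## Numerical choices

* Strict inequalities at the detection threshold and at the DCIS 2-mm rule;
  inclusive inequality (with $10^{-9}$ slack) at the 0.84 contact cutoff.
* Coefficient ties break toward the smaller candidate.
* The Gaussian halo is convolved by FFT; magnitudes below $10^{-6}$ are
  clipped so the kernel's finite support is exact.
* All randomness flows from a single integer seed per generated object;
  generation saves and restores the caller's RNG state, and identical
  configurations produce byte-identical cohorts (tested).
* Percentages are kept as exact fractions internally and rounded only for
  display.

## Problem sizes used by the tests

The packaged tests exercise the pipeline at reduced resolution (48-px
grids, area guard 2 px) with cohorts of 2--150 patients; the
calibration-consistency check uses 150 patients (~1,800 surfaces,
leave-one-patient-out). The default configuration -- 256-px grids, 40
patients, 12 surfaces each -- matches the scale of the motivating cohort
and runs the full pipeline in a few minutes. The acceptance script renders
50 transected specimens at the default 256-px resolution.

## What the simulator does not capture

Real cavity surfaces are curved and scanned freehand; the generator renders
flat, independent fields. Histopathology sampling error (only a few 5-µm
sections are examined per specimen) is not modelled: ground truth is exact.
Tumor prevalence is independent across surfaces, whereas real intermediate
and final surfaces of one patient are correlated. Benign-hotspot intensity
and occult-tumor exposure distributions are the package's own constructs,
chosen for operating-point consistency, not measured tissue properties.
Passing tests therefore demonstrate that the *analysis* behaves correctly
under the assumed statistical structure -- not that the device performs as
reported on real tissue.
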