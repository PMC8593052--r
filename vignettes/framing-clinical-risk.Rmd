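---
title: "Temporal framing of clinical risk prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal framing of clinical risk prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A risk prediction model on longitudinal inpatient data is not defined by its
learner alone. Before training, the admission stream must be converted into
supervised samples, and that conversion — the *framing* — fixes when
predictions are made, which retrospective data each prediction may use, and
how far ahead an outcome counts as positive. Two models with identical
learners and identical cohorts but different framings can differ by an order
of magnitude in apparent precision, simply because the framings induce
different class balances and different mixtures of easy and hard samples.

`framingbench` implements the machinery to study this effect end to end on a
sepsis prediction task: a cohort data model, a Sepsis-3 onset labeler, four
framing structures, a fixed feature pipeline, a calibration-aware evaluation
bench, and a synthetic cohort generator that plants ground-truth sepsis
episodes.

All times are continuous hours relative to an arbitrary cohort epoch. Every
window in the package is half-open, `(a, b]`: a measurement or onset exactly
at a boundary belongs to exactly one window. This single convention decides
all tie cases — a measurement exactly at the prediction time is observable; an
onset exactly at the end of the prediction window is positive.

## Labeling: Sepsis-3

An admission is labeled septic when *suspected infection* and *acute organ
dysfunction* co-occur.

**Suspected infection (SI).** A culture sample followed by an antibiotic
administration within 72 h, or an antibiotic followed by a culture within
24 h. Every qualifying pair yields an SI event whose *index time* is the
earlier member of the pair. The texts that operationalize Sepsis-3 leave the
index convention open; we use the earlier member because both directions of
the pair window are anchored on it, and because only the earliest resulting
onset is ever reported, so over-generating SI events is harmless. Multiple
antibiotic administrations are treated as independent events rather than
collapsed into courses.

**Organ dysfunction.** The SOFA score (integers 0–24 on an hourly grid,
forward-filled step function) must rise by at least 2 points inside the
window from 48 h before to 24 h after an SI index time, clipped to the
admission. "Acute increase" is made precise as an increase relative to the
*running minimum* of the score within the window up to the candidate time:
time `t` qualifies when `SOFA(t) − min{SOFA(u) : u ≤ t, u in window} ≥ 2`.
The onset time is the earliest qualifying `t` over all SI events. The
running-minimum baseline detects a genuine deterioration regardless of where
in the window it starts, while a fixed window-start baseline would miss
rises that follow an initial recovery.

The single most consequential ambiguity in this labeling is whether "onset"
means the SI index time or the time the SOFA criterion is met; we chose the
SOFA-increase time, since that is the moment organ dysfunction is
established, and the SI window is a search region rather than a clinical
event.

SOFA provenance is pluggable. `sofa_from_table()` accepts precomputed
scores; `compute_sofa_series()` scores raw measurements against a component
table covering the organ systems observable from the packaged general-ward
schema (platelets, bilirubin, creatinine, a derived mean arterial pressure,
and arterial pO2 with thresholds expressed on the raw kPa value assuming
ambient air). Components with no data score 0 — *missing-as-normal* — which
is the only defensible convention on general wards where Glasgow Coma Scale
and vasopressor data are simply not collected.

## The four framing structures

All structures share the window vocabulary: an **observation window**
(default 12 h) behind the prediction time, a **lead window** (default 0 h),
and a **prediction window** (default 12 h) ahead of it. A sample is positive
iff the onset lies in `(t + lead, t + lead + prediction window]`.

* **Fixed time to onset** — positives get exactly one sample at
  `onset − 12 h` (dropped if it precedes admission); negatives get one
  sample at a seeded uniform time in `(admit, discharge]`. This is a
  case-control design: it produces the mildest imbalance, but its
  prediction times depend on future information, so its headline numbers do
  not translate to deployment.
* **Sliding window** — prediction times at
  `admit + observation window + k · shift` (shift 6 h) up to and including
  discharge. The first prediction time waits for a full observation window;
  starting earlier would systematically truncate the first windows and
  conflate framing effects with missing-data effects.
* **Sliding window with dynamic inclusion** — the sliding grid restricted
  to times at or after the first hourly grid point with SOFA > 0. We keep
  the *grid* alignment rather than re-anchoring the shift sequence at the
  inclusion time: that makes the dynamic sample set an exact subset of the
  sliding sample set with identical positives, so the two structures differ
  only in how many easy negatives they retain — which is precisely the
  comparison the structure exists to make. (Re-anchoring at the inclusion
  time is the other defensible reading; it breaks the subset relation and
  makes the two structures' positives non-comparable.)
* **On clinical demand** — one sample per EWS assessment, at the
  assessment's time. No shift arithmetic; the physician sets the sampling
  rate.

For positive admissions, samples at or after onset are dropped in the three
repeated-sampling structures. Emitting them would create samples whose label
is ambiguous (the disease is already present), and no clinical question is
answered by predicting an event that has happened. Prediction windows that
extend past discharge for negatives still yield label 0; right-censoring is
deliberately ignored, as in the framing designs this package reproduces.

## Feature pipeline

Each sample's observation window is processed in four fixed steps:

1. **Hourly means** — within 1 h bins anchored at the prediction time and
   counted backwards (bins are sample-relative, not clock-aligned, so two
   samples of the same admission at different times bin identically relative
   to their own anchor).
2. **Two 6 h timesteps** — `late` (most recent 6 h) and `early`, each the
   mean of its available hourly values.
3. **Forward/backward imputation** — a missing late value is copied from
   early, then a missing early value from late. Idempotent by construction.
4. **Assembly** — 25 value features (the late timestep: recency maximizes
   clinical relevance) plus 25 Δ features (late − early), 50 in total. A Δ
   from a single imputed source is exactly 0 — "no observed trend", not a
   fabricated one.

Residual missingness survives: tree learners that handle missing values
natively (xgboost) consume it directly; families that cannot (ranger
forests, logistic regression) receive *train-fitted* median imputation
inside the model adapter, and the logistic adapter additionally train-fitted
standardization. Nothing is imputed or scaled globally — that would leak
test-set statistics into training.

Missingness is reported from *pre-imputation* observability: a value feature
counts as missing when neither timestep held data, a Δ feature when either
was unobserved. This is why Δ missingness always dominates value missingness
in `missingness_report()`, and why the on-clinical-demand framing — whose
windows end at the very moment vitals are recorded — shows near-zero vital
missingness while clock-driven framings do not.

## Evaluation bench

**Folds.** Five-fold cross-validation over *patients*, not samples: each
fold holds out ~20% of patients, split in half into validation (early
stopping for boosting only) and test; all samples of a patient share the
patient's role. Patient-level grouping is the leakage guard — with repeated
sampling structures, samples of one admission are heavily correlated, and a
sample-level split would grade memorization.

**Metrics.** AUROC via the midrank statistic (tie-robust); AUPRC via step
integration of the precision–recall curve over distinct thresholds; the
stratified Brier score, `100 · mean((1 − p)²)` over positives and
`100 · mean(p²)` over negatives, which keeps majority-class performance from
masking minority-class calibration; and the average calibration error (ACE):
10 equal-width, right-closed probability bins, per non-empty bin the
absolute gap between observed event fraction and mean predicted probability,
averaged *unweighted* over non-empty bins. Choices the metric definitions
leave open, fixed here: 10 bins; empty bins excluded (including them would
require inventing a gap for no data); "observed fraction" is the event rate,
the standard reading for binary risk scores; probability 0 falls in the
first bin. Per-fold values are summarized as mean ± t(0.975, k−1) · sd/√k.

**Models.** Extra trees and random forests (ranger; extra trees is ranger
with `splitrule = "extratrees"`, one random split per candidate variable, no
bagging), gradient boosting (xgboost, 300 rounds with early stopping on the
validation patients), and logistic regression (`stats::glm`).
Hyperparameters are the backends' defaults plus a fixed seed: this bench
compares framings, and per-cell tuning would confound that comparison.

## The synthetic cohort

The generator emulates the statistical structure the pipeline assumes, not
any real population's epidemiology. Its defaults are the package's study
conditions; they were chosen to land the benchmark in the realistic
discrimination regime for ward-based sepsis prediction (AUROC roughly
0.75–0.95) and are not meant to be re-tuned per experiment.

* **Admissions.** Log-normal length of stay (median ≈ 72 h, log-sd 0.6)
  truncated to the 24 h–50 d inclusion band; ~10% of patients contribute two
  admissions; planted positives are exactly
  `floor(n · prevalence + 0.5)` of admissions (round half up — a
  deterministic count keeps fixture prevalences exact), default prevalence
  6.25%.
* **Sepsis episodes.** Onset on the hourly grid, ≥ 20 h after admission and
  ≥ 4 h before discharge. Evidence planted around it: a culture at
  onset − 2 h and an antibiotic at onset + 1 h (a qualifying SI pair); a
  SOFA series at 0 until onset − 16 h, 1 until onset, and 4 after (the ≥ 2
  rise at onset); and a deterioration ramp in the vitals and
  sepsis-relevant labs (rising pulse, respiratory rate, temperature, CRP,
  lactate, creatinine; falling blood pressures, SpO2, platelets) over the
  60 h before onset, scaled by a per-patient severity factor
  (log-normal, median ≈ 0.8 — a sizeable minority present atypically).
* **The drift saturates 16 h before onset.** This "compensated
  deterioration" plateau is a deliberate design choice: windows ending
  anywhere in the final plateau carry comparable signal, so differences
  between framings reflect their sampling policies (sample counts, class
  balance, negative hardness) rather than horizon-dependent signal
  strength. With a ramp running into onset itself, near-onset framings
  would be graded on an easier per-sample task, which is not the comparison
  of interest.
* **Non-septic deterioration.** All admissions can have transient episodes
  (triangular profile, 12–48 h wide, intensity 0.3–1.1 of the sepsis drift
  vector; roughly one per ~4 days of stay, slightly rarer in positives).
  These are the fevers, arrhythmias and exacerbations that make real ward
  negatives hard, and they are what keeps the benchmark honest: framings
  that sample more often sample more of them.
* **Measurements.** EWS assessments every ~8 h (jitter 2 h), with two
  additional assessments during any deterioration episode and near-onset
  reassessments for septic patients — the physician-driven trigger the
  on-clinical-demand framing relies on. All six vitals are recorded at each
  assessment (3% dropout; 12% for temperature), plus sparse off-schedule
  vitals. Laboratory parameters are drawn at irregular ~daily intervals;
  arterial blood-gas parameters exist in only ~35% of admissions — the
  heavy, structured missingness the imputation pipeline is built for.
* **Decoys.** ~8% of negative admissions get a non-qualifying event — a lone
  antibiotic, or a culture/antibiotic pair 80 h apart — to exercise the SI
  pairing logic's rejection branches. 70% of negative admissions carry a
  constant mild SOFA of 1 (chronic low-grade dysfunction), which is what the
  dynamic-inclusion framing keeps sampling.

What the generator does *not* emulate: real marginal distributions or
correlations between parameters, comorbidity structure, treatment effects
(antibiotics do not alter the planted trajectory), diurnal rhythms, or
documentation artifacts. A passing benchmark on this cohort demonstrates
that the pipeline's mechanics — labeling, sampling, leakage guards,
imbalance effects — behave as designed; it is not evidence that any model
would reach similar numbers on real wards.

With these conditions, the qualitative relationships expected from framing
theory reproduce stably at ~2000 admissions: the negatives-to-positives
ratio increases strictly in the order fixed time to onset < on clinical
demand < dynamic inclusion < sliding window; AUPRC for a fixed boosting
family decreases strictly along the same order; AUROC varies far less than
AUPRC across framings. The package's tests assert exactly these orderings
(`tests/testthat/test-acceptance.R`), and `scripts/acceptance.R` recomputes
them from scratch for any seed.

## Numerical and degenerate-input conventions

* SOFA grids are hourly, anchored at the admission start; grid points
  before the first recorded score carry the first score backward.
* An admission shorter than the observation window yields no sliding
  samples; an admission with no EWS yields no on-demand samples; a positive
  whose onset is within 12 h of admission yields no fixed-time sample.
  These degenerate cases are silent by design — they are cohort facts, not
  errors.
* A benchmark cell whose test split lacks one of the classes is reported as
  `NA` with a warning; the run continues.
* Class-ratio text `1:N` uses `N = round(negatives/positives)` and is
  undefined (NA) with zero positives.
* All stochastic functions take explicit seeds (`withr::with_seed`), so no
  call mutates the caller's RNG state.

## Known limitations

* Sequential learners (RNN/TCN-style) and the four framing structures that
  suit them (sequential with/without prediction windows, at-event, random
  time to onset) are out of scope; the sample tables produced here are the
  natural input to such extensions.
* The SOFA component table covers only the organ systems observable in the
  packaged schema; CNS and vasopressor-dependent cardiovascular points are
  structurally absent, so computed SOFA totals are floor estimates.
* The labeler evaluates measurements only within the admission interval;
  pre-admission laboratory values are rejected at validation.
* No alarm-level evaluation (thresholds, silencing policies,
  alarms-per-detection curves): the bench reports probabilistic metrics
  only.
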