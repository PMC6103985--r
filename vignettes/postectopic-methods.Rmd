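---
title: "Methods: post-ectopic beat analysis for fluid responsiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-ectopic beat analysis for fluid responsiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postectopic)
```

## The measurement idea

An extrasystole perturbs preload for exactly one heartbeat. The premature
beat starts before the ventricle has filled, ejects poorly, and is followed
by a compensatory pause during which filling is prolonged and the ectopic
beat's residual volume is still in the ventricle. The first sinus beat after
the ectopic — the *post-ectopic beat* — therefore contracts under increased
preload. On the steep portion of the Frank–Starling curve the extra preload
raises stroke volume and arterial pressure; on the plateau it does not. The
size of the post-ectopic change in pressure-derived variables is thus a
candidate predictor of whether a fluid bolus would raise stroke volume,
without giving any fluid.

The quantity computed throughout is, per variable
(SBP, PEP, PP, dP/dt max):

> post-ectopic beat value − median of the ten sinus beats preceding the
> extrasystole,

as an absolute change and as a percentage of the baseline median
(`post_ectopic_delta()`). Per patient, the ≤ 10 most recent *eligible*
extrasystoles inside a 30-minute window are aggregated by the median
(`aggregate_patient()`). A patient without eligible extrasystoles gets no
summary row: the method is simply not applicable there, and the pipeline
says so in its QC log rather than imputing anything.

## Eligibility rules

An ectopic beat is *eligible* (`find_eligible_ectopics()`) when

1. the ten beats immediately preceding it are all sinus-labelled,
2. its coupling interval is at most 80 % (inclusive) of the median RR of
   those ten beats,
3. the following beat exists and is the post-ectopic beat, and
4. it lies inside the lookback window ending at the last annotated beat.

Beat labels come from `classify_beats()`: RR ≤ 150 ms is an artifact, a
beat whose RR is ≤ 80 % of the reference sinus RR is ectopic (the reference
is the median of the up-to-10 most recent sinus RRs by default; the single
last sinus RR with `coupling_ref = "last"`), the beat after an ectopic is
post-ectopic, and unexplained long pauses are artifacts. The first eleven
beats of a record are never labelled ectopic — there is not enough rhythm
context to call prematurity.

## Waveform processing

* **Resampling.** All beat-level measurements run at 1 kHz (1 ms
  resolution). Lower-rate records are upsampled by cubic spline
  (`resample_to_1khz()`); input samples are reproduced exactly at
  coincident grid points. Downsampling is out of scope and refused.
* **R-peaks.** A Pan-Tompkins-style detector (`detect_r_peaks()`):
  5–30 Hz zero-phase band-pass, squared derivative, 150 ms moving-window
  integration, adaptive threshold with a 250 ms refractory period, then
  refinement to the raw ECG extremum.
* **Pulse delineation.** The pulse foot is found by the intersecting-tangent
  method (`delineate_beat()`): the systolic upstroke tangent — estimated by
  least squares over the central 25–75 % of the pressure rise, which is
  unbiased under additive noise, unlike the single maximum of a noisy
  derivative — is intersected with the horizontal line through the
  preceding pressure minimum. PEP is R-peak to foot (it includes vascular
  transit time, hence a baseline around 212 ms at the radial site); SBP,
  DBP, PP and dP/dt max (25 ms Savitzky–Golay differentiator) follow from
  the foot.
* **Per-variable validity.** A waveform cut near the diastolic level
  invalidates the foot-dependent variables (PEP, PP, DBP, dP/dt) but leaves
  SBP usable; an absent upstroke invalidates everything. Aggregation skips
  missing values per variable and reports fully excluded variables, so one
  damaged channel segment does not silently discard a patient.

## The statistics layer

`fluidresp()` is the modelling entry point: a formula interface
(`dsv_rel_pct ~ dsbp_abs + ...`) over a one-row-per-patient summary table.
For every predictor and every SV-response threshold (10 % primary, 15 %
secondary; non-strict `>=` by default) it computes

* the ROC area as the rank-based Mann–Whitney statistic (ties count one
  half), with a DeLong placement-variance confidence interval clipped to
  [0, 1] — orientation is fixed a priori (larger score ⇒ responder), never
  auto-flipped;
* the Youden-optimal cut-point over all midpoints of adjacent unique scores
  plus the two extreme classify-all/classify-none cut-points, under the
  rule "positive iff score > threshold", ties broken toward higher
  specificity;
* sensitivity, specificity, PPV and NPV at that cut-point, and
* a responder vs non-responder comparison by pooled two-sample t at the
  primary threshold.

`two_sample_t_pooled()` accepts either raw vectors or published
mean/SD/n summary statistics; both paths agree to machine precision, which
is what lets printed group tables be checked directly.

## The synthetic-data generator

No patient-level data ship with the package; the generator defines the
study conditions the pipeline is verified under. It has two tiers.

**Cohort tier** (`simulate_cohort_summaries()`) draws aggregated per-patient
deltas directly: within each response group each variable is normal with the
configured mean and SD, the relative delta is derived from a per-patient
baseline draw (baselines are redrawn while below 20 % of the group mean so
relative deltas stay finite), and the relative SV change is uniform within
the group's range. The default parameters encode a 20/6 non-responder/
responder ICU cohort, e.g. an absolute post-ectopic SBP change of
−0.1 (5.6) vs 5.9 (6.6) mmHg.

**Patient tier** (`simulate_patient_waveforms()`) renders two-channel
ECG/ABP records with per-beat ground truth. All functional forms are this
package's inventions, chosen to emulate the narrative physiology:

* per-beat preload = operating point + `preload_gain` × (fractional change
  of filling time) + `resid_bonus` after an ectopic's poor ejection;
* stroke volume follows a logistic Frank–Starling surrogate
  (`starling_sv()`); the premature beat's SV is additionally scaled by its
  truncated filling fraction, so it ejects poorly in *both* Starling
  regimes — without this penalty a plateau (non-responder) patient would
  show a spurious post-ectopic SBP rise driven purely by diastolic run-off
  timing;
* pulse pressure = SV / arterial compliance; diastole decays exponentially
  (windkessel) toward an asymptote; the rendered pulse has a linear
  upstroke with a slope-continuous parabolic cap, so the
  intersecting-tangent foot of the rendered wave coincides with the
  programmed onset;
* PEP decreases with preload scaled by `pep_preload_coef_ms` (negative, so
  post-ectopic PEP rises), plus beat-to-beat noise;
* ventricular ectopics get a full compensatory pause (coupling + pause =
  2 × local RR) and a wide QRS without a P wave; supraventricular ectopics
  reset the sinus node;
* output is emitted at 125 Hz by default so the pipeline's own resampling
  path is always exercised.

**Calibration.** The responder defaults (`preload_gain = 0.5`,
`resid_bonus = 0.35`, operating point 0.66 on a unit-slope-0.7 logistic)
were set once, by scanning the ground-truth mean post-ectopic SBP change to
the +6 mmHg design target, and then frozen. The non-responder configuration
(`sim_nonresponder_config()`) moves the operating point onto the plateau
and changes nothing else. The generator is a fixed experimental condition,
not a tuning dial: its parameters are not adjusted in response to test
outcomes.

## Verification strategy and problem sizes

The test suite verifies each layer against an independent oracle:

* ROC areas against exhaustive pairwise counting on random tied cohorts,
  and DeLong variances against `pROC`;
* Youden thresholds against an exhaustive grid (this check caught a real
  defect during development: without the extreme cut-points, reversed
  separations were scored worse than "classify everyone negative");
* pooled-t summary-statistic path against `stats::t.test` on raw data;
* beat delineation against a programmed synthetic pulse with known
  landmarks, and against the simulator's per-beat ground truth (median PEP
  error under 2 ms, SBP under 0.5 mmHg);
* the full pipeline against ground-truth aggregated deltas on 20 simulated
  patients (360 s records), and end-to-end discrimination on a 100+100
  responder/non-responder cohort (240 s records, AUC of the absolute SBP
  delta above 0.7).

Record lengths and cohort sizes in the tests are package choices balancing
statistical resolution against a single-CPU runtime budget of a few
minutes; they are not physiological claims.

## Limitations

* The simulator's PEP mechanism is deliberately low-noise and tied to
  preload; with the default parameters the *between-group* separation of
  the PEP delta is weak even though the within-patient post-ectopic PEP
  rise is reliable. Discrimination claims in the tests therefore rest on
  the SBP delta.
* Artifact handling covers pinned (cut) waveforms, implausibly short RR
  intervals and unexplained pauses; it is not a general arrhythmia
  classifier (atrial fibrillation, bigeminy runs longer than couplets, and
  paced rhythms are out of scope).
* `aggregate_patient()` treats the SV measurement as given; SV monitor bias
  is not modelled beyond additive reading noise.
* Thresholds reported by `youden_threshold()` can be `Inf` when no
  cut-point beats classifying everyone negative; downstream code must not
  assume finiteness.
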