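# postectopic

Fluid-responsiveness prediction from post-ectopic beat hemodynamics.

An extrasystole (ectopic beat) transiently perturbs cardiac preload: the
premature beat ejects poorly and the compensatory pause lengthens ventricular
filling, so the first sinus beat after the ectopic contracts under increased
preload — a one-heartbeat, intervention-free preload challenge. On the steep
portion of the Frank–Starling curve this raises stroke volume and arterial
pressure; on the plateau it does not. `postectopic` quantifies the
post-ectopic change of arterial-pressure variables (SBP, PEP, PP, dP/dt max)
relative to the median of the ten preceding sinus beats and evaluates those
changes as predictors of a stroke-volume (SV) response to a fluid bolus.

The package contains:

* **Signal I/O** — delimited-text ECG/ABP waveform records, SV tables,
  cubic-spline resampling to 1 kHz (`read_waveform()`, `resample_to_1khz()`,
  `sv_series()`).
* **Beat detection** — Pan-Tompkins-style R-peak detection, beat
  classification (sinus / ectopic / post-ectopic / artifact, coupling
  interval ≤ 80 % of the reference sinus RR, boundary inclusive) and
  extrasystole eligibility rules (`detect_r_peaks()`, `classify_beats()`,
  `find_eligible_ectopics()`).
* **Beat features** — intersecting-tangent pulse-foot delineation with a
  least-squares tangent over the central upstroke, per-beat SBP, DBP, PP,
  MAP, dP/dt max and PEP with per-variable validity flags
  (`delineate_beat()`, `features_for_record()`).
* **Post-ectopic deltas** — change of the post-ectopic beat versus the
  ten-beat baseline median, aggregated per patient over the ≤ 10 most recent
  eligible extrasystoles in a 30-minute window (`post_ectopic_delta()`,
  `aggregate_patient()`).
* **Cohort statistics** — rank-based ROC AUC with DeLong confidence
  intervals, Youden-index thresholds, confusion statistics, pooled/paired t
  tests, Spearman correlation (`roc_auc()`, `youden_threshold()`, …).
* **The classification model** — `fluidresp()` fits the full predictor ×
  SV-threshold grid and returns a classed object with `print`, `summary`,
  `coef`, `predict`, `plot` and `simulate` methods; `run_classification()`
  is the all-standard-predictors wrapper.
* **A two-tier synthetic-data generator** — `simulate_cohort_summaries()`
  draws patient-summary cohorts with a published group structure;
  `simulate_patient_waveforms()` renders beat-resolved ECG/ABP waveforms
  from a preload mechanism (logistic Frank–Starling stroke volume,
  windkessel diastole, compensatory pauses) together with per-beat ground
  truth, so the entire pipeline is testable without patient data.

## Worked example

Cohort tier — simulate 26 patients (20 non-responders, 6 responders) and fit
the classification model:

```r
library(postectopic)
s <- simulate_cohort_summaries(cohort_sim_config(seed = 1))
fit <- run_classification(s)
fit
#> Fluid-responsiveness classification from post-ectopic beat changes
#> Call: run_classification(summaries = s)
#> Patients: 26  (responders at 10% SV threshold: 6)
#> ROC areas (primary threshold):
#>           auc_10
#> dsbp_abs    0.95
#> dsbp_rel    0.94
#> dpep_abs    0.92
#> dpep_rel    0.91
#> dpp_abs     0.71
#> dpp_rel     0.64
#> ddpdt_abs   0.62
#> ddpdt_rel   0.65
```

`summary(fit)` adds DeLong confidence intervals, Youden-optimal thresholds
with sensitivity/specificity/PPV/NPV, and the responder vs non-responder
group comparison; for this seed the absolute SBP change separates the groups
at −0.3 (4.7) vs 8.9 (3.6) mmHg, pooled-t p < 0.01.

Waveform tier — render a two-minute ECG/ABP record with extrasystoles and
run the full pipeline on it:

```r
sim <- simulate_patient_waveforms(
  patient_sim_config(duration_s = 120, p_ectopic = 0.08, seed = 8),
  patient_id = "SIM001")
sim$record
#> <waveform_record> patient SIM001: 15001 samples @ 125 Hz (120.000 s)

an <- analyze_record(sim$record, sim$sv)
an$summary[, c("patient_id", "n_eligible", "dsbp_abs", "dsv_rel_pct",
               "responder_10")]
#>   patient_id n_eligible dsbp_abs dsv_rel_pct responder_10
#> 1     SIM001          7 4.991037    14.13717         TRUE
```

Seven extrasystoles passed the eligibility rules; the aggregated post-ectopic
SBP rise of +5.0 mmHg correctly flags this simulated fluid responder
(measured SV response +14.1 %). `analyze_cohort()` stacks such per-patient
summaries and fits `fluidresp()` on them; `plot(fit)` draws the ROC curves.

A thin command-line front end is installed as `exec/postectopic`
(`init-config`, `simulate`, `analyze`, `stats` subcommands).

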