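Package: postectopic
Title: Fluid Responsiveness Prediction from Post-Ectopic Beat Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects extrasystoles (ectopic beats) in ECG recordings, quantifies
    the post-ectopic change in arterial-pressure-derived variables (systolic
    blood pressure, pre-ejection period, pulse pressure, maximal systolic
    upstroke slope) relative to the median of the ten preceding sinus beats,
    and evaluates those changes as predictors of a stroke-volume response to a
    fluid bolus. Includes beat delineation of invasive arterial pressure
    waveforms, ROC analysis with DeLong confidence intervals and Youden-index
    thresholds, and a two-tier synthetic-data generator (cohort summaries and
    beat-resolved ECG/ABP waveforms with ground truth) so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
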