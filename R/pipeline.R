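#' Analyze one patient's waveform record end to end
#'
#' Runs the full single-patient pipeline: resample to 1 kHz, detect R-peaks,
#' classify beats, delineate arterial pulses, find eligible extrasystoles,
#' compute post-ectopic deltas and aggregate them into one summary row.
#' Every QC exclusion (artifact beats, invalid pulse variables, ineligible
#' or surplus extrasystoles, absent extrasystoles) is recorded in the
#' returned log.
#'
#' @param rec A [waveform_record()] (any rate up to 1000 Hz).
#' @param sv An [sv_series()] for the same patient, or `NULL`.
#' @param window_s Lookback window (s) for eligible extrasystoles.
#' @param max_es Maximum number of most recent extrasystoles aggregated.
#' @param coupling_max Prematurity/eligibility threshold.
#' @param coupling_ref Reference RR convention, see [classify_beats()].
#' @param strict Strict (`>`) responder threshold comparison.
#' @return A list of class `patient_analysis`: `summary` (one-row
#'   `patient_summary`, or `NULL` when the method is not applicable),
#'   `beats`, `features`, `eligibles`, `deltas` and `qc_log` (character).
#' @export
analyze_record <- function(rec, sv = NULL, window_s = 1800, max_es = 10L,
                           coupling_max = 0.80,
                           coupling_ref = c("median10", "last"),
                           strict = FALSE) {
  stopifnot(inherits(rec, "waveform_record"))
  coupling_ref <- match.arg(coupling_ref)
  pid <- rec$patient_id
  log <- character()
  note <- function(...) log <<- c(log, paste0("[", pid, "] ", sprintf(...)))

  rec1k <- resample_to_1khz(rec)
  beats <- detect_r_peaks(rec1k)
  beats <- classify_beats(beats, coupling_max = coupling_max,
                          coupling_ref = coupling_ref)
  n_art <- sum(beats$label == "artifact")
  if (n_art) note("%d beat(s) flagged artifact", n_art)

  feats <- features_for_record(rec1k, beats)
  n_cut <- sum(feats$reason == "waveform cut")
  if (n_cut) note("%d beat(s) with waveform cut near the diastolic level", n_cut)
  n_inv <- sum(!feats$valid) - n_cut
  if (n_inv > 0) note("%d beat(s) with undetectable pulse landmarks", n_inv)

  elig <- find_eligible_ectopics(beats, window_s = window_s,
                                 coupling_max = coupling_max)
  n_ect <- sum(beats$label == "ectopic")
  if (n_ect > nrow(elig))
    note("%d of %d ectopic beat(s) failed eligibility", n_ect - nrow(elig), n_ect)
  if (nrow(elig) > max_es)
    note("using the %d most recent of %d eligible extrasystoles",
         max_es, nrow(elig))

  deltas <- deltas_for_record(feats, elig)
  summary_row <- if (nrow(deltas)) {
    suppressMessages(aggregate_patient(deltas, sv, patient_id = pid,
                                       max_es = max_es, window_s = window_s,
                                       end_time_s = rec1k$duration_s,
                                       strict = strict))
  } else {
    note("no eligible extrasystoles: method not applicable")
    NULL
  }
  if (!is.null(summary_row) && nzchar(summary_row$excluded_vars))
    note("variable(s) excluded for QC: %s", summary_row$excluded_vars)
  if (!is.null(sv)) {
    for (q in attr(sv, "qc")) note("SV QC: %s", q)
  } else note("no SV series: responder status unknown")

  structure(list(summary = summary_row, beats = beats, features = feats,
                 eligibles = elig, deltas = deltas, qc_log = log),
            class = "patient_analysis")
}

#' Analyze a cohort of waveform records and classify fluid responsiveness
#'
#' Runs [analyze_record()] per patient, stacks the per-patient summaries and
#' fits the [fluidresp()] classification model on them. Patients without SV
#' data or without eligible extrasystoles are excluded from classification
#' and logged.
#'
#' @param records A list of [waveform_record()]s (or a list of per-patient
#'   simulator outputs from [simulate_patient_waveforms()], whose bundled SV
#'   series are then used).
#' @param sv_list Named list of [sv_series()] keyed by patient id (ignored
#'   for simulator outputs).
#' @param ... Passed to [analyze_record()].
#' @param classify Fit the classification model when at least two patients
#'   of each response class are available.
#' @return A list of class `cohort_analysis`: `summaries` (patient-summary
#'   data frame), `fit` (a `fluidresp` object or `NULL`), `analyses`
#'   (per-patient `patient_analysis` lists) and `qc_log`.
#' @export
analyze_cohort <- function(records, sv_list = NULL, ..., classify = TRUE) {
  analyses <- list(); log <- character()
  for (item in records) {
    if (is.list(item) && !inherits(item, "waveform_record") &&
        !is.null(item$record)) {
      rec <- item$record; sv <- item$sv
    } else {
      rec <- item
      sv <- if (!is.null(sv_list)) sv_list[[rec$patient_id]] else NULL
      if (is.null(sv) && !is.null(sv_list))
        log <- c(log, paste0("[", rec$patient_id,
                             "] missing from SV table: excluded from classification"))
    }
    an <- analyze_record(rec, sv = sv, ...)
    analyses[[rec$patient_id]] <- an
    log <- c(log, an$qc_log)
  }
  rows <- Filter(Negate(is.null), lapply(analyses, `[[`, "summary"))
  summaries <- if (length(rows)) do.call(rbind, rows) else NULL
  fit <- NULL
  if (classify && !is.null(summaries) &&
      sum(summaries$responder_10, na.rm = TRUE) >= 2L &&
      sum(!summaries$responder_10, na.rm = TRUE) >= 2L) {
    fit <- run_classification(summaries)
  } else if (classify) {
    log <- c(log, "classification skipped: fewer than 2 patients per response class")
  }
  structure(list(summaries = summaries, fit = fit, analyses = analyses,
                 qc_log = log),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  n_tot <- length(x$analyses)
  n_ok <- if (is.null(x$summaries)) 0L else nrow(x$summaries)
  cat(sprintf("<cohort_analysis> %d patient(s), %d with eligible extrasystoles\n",
              n_tot, n_ok))
  if (!is.null(x$fit)) print(x$fit) else cat("No classification fit.\n")
  invisible(x)
}
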