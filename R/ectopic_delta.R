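# variable -> (feature column, validity column) mapping used throughout
.delta_vars <- c(sbp = "sbp_mmHg", pep = "pep_ms", pp = "pp_mmHg",
                 dpdt = "dpdt_max")
.delta_valid <- c(sbp = "valid_sbp", pep = "valid_pep", pp = "valid_pp",
                  dpdt = "valid_dpdt")

#' Post-ectopic change relative to the ten preceding sinus beats
#'
#' The core statistic: for each variable (SBP, PEP, PP, dP/dt max) the
#' difference between the post-ectopic beat's value and the median of the ten
#' sinus beats preceding the extrasystole, as an absolute change in native
#' units and a relative change in percent of the baseline median. A variable
#' with any invalid baseline beat or an invalid post-ectopic value is
#' reported missing for this extrasystole (no imputation).
#'
#' @param baseline A `beat_features` data frame with exactly 10 rows: the
#'   sinus beats immediately preceding the ectopic, oldest first.
#' @param post A one-row `beat_features` data frame: the post-ectopic beat.
#' @param ectopic_time_s Optional time stamp (s) of the extrasystole,
#'   carried through for windowing.
#' @return A one-row data frame with `dsbp_abs`, `dsbp_rel`, `dpep_abs`,
#'   `dpep_rel`, `dpp_abs`, `dpp_rel`, `ddpdt_abs`, `ddpdt_rel`, the baseline
#'   medians (`base_sbp`, `base_pep`, `base_pp`, `base_dpdt`) and
#'   `ectopic_time_s`.
#' @export
#' @examples
#' # a +6 mmHg post-ectopic SBP rise over a 120 mmHg baseline is +5 %
post_ectopic_delta <- function(baseline, post, ectopic_time_s = NA_real_) {
  baseline <- as.data.frame(baseline)
  post <- as.data.frame(post)
  if (nrow(baseline) != 10L)
    stop("baseline must contain exactly 10 beats, got ", nrow(baseline))
  if (nrow(post) != 1L) stop("post must be a single beat")
  out <- list(ectopic_time_s = ectopic_time_s)
  for (v in names(.delta_vars)) {
    col <- .delta_vars[[v]]; okcol <- .delta_valid[[v]]
    bvals <- baseline[[col]]; bok <- baseline[[okcol]]
    pval <- post[[col]]; pok <- post[[okcol]]
    if (all(bok) && !anyNA(bvals) && isTRUE(pok) && !is.na(pval)) {
      med <- stats::median(bvals)
      dabs <- pval - med
      drel <- if (med != 0) 100 * dabs / med else NA_real_
    } else {
      med <- NA_real_; dabs <- NA_real_; drel <- NA_real_
    }
    out[[paste0("base_", v)]] <- med
    out[[paste0("d", v, "_abs")]] <- dabs
    out[[paste0("d", v, "_rel")]] <- drel
  }
  as.data.frame(out)
}

#' Aggregate a patient's post-ectopic deltas and attach the fluid response
#'
#' Keeps the most recent `max_es` extrasystoles inside the lookback window,
#' aggregates each variable as the median of its available (non-missing)
#' per-ectopic deltas, and labels the patient a fluid responder when the
#' relative stroke-volume change meets the 10 % (and, secondarily, 15 %)
#' threshold. A variable with zero contributing extrasystoles is listed in
#' `excluded_vars`; a patient with no eligible extrasystole yields no summary
#' row (the method is not applicable) and `NULL` is returned with a message.
#'
#' @param deltas A data frame of [post_ectopic_delta()] rows, time-ordered
#'   (oldest first); may have zero rows.
#' @param sv An [sv_series()] for the same patient, or `NULL` when no fluid
#'   challenge data exist (responder flags then `NA`).
#' @param patient_id Patient identifier for the summary row.
#' @param max_es Maximum number of most recent extrasystoles to use.
#' @param window_s Lookback window (s) ending at `end_time_s`.
#' @param end_time_s Reference end time (s); defaults to the last ectopic.
#' @param strict If `TRUE`, responder thresholds are strict (`>`); default is
#'   non-strict (`>=`).
#' @return A one-row `patient_summary` data frame: `patient_id`,
#'   `n_eligible`, the eight aggregated deltas plus baseline medians,
#'   `sv_baseline_ml`, `sv_post_ml`, `dsv_rel_pct`, `responder_10`,
#'   `responder_15` and `excluded_vars` (comma-separated), or `NULL`.
#' @export
aggregate_patient <- function(deltas, sv = NULL, patient_id = "unknown",
                              max_es = 10L, window_s = 1800,
                              end_time_s = NULL, strict = FALSE) {
  deltas <- as.data.frame(deltas)
  if (!nrow(deltas)) {
    message("patient ", patient_id,
            ": no eligible extrasystoles - method not applicable")
    return(NULL)
  }
  if (is.unsorted(deltas$ectopic_time_s, na.rm = TRUE))
    deltas <- deltas[order(deltas$ectopic_time_s), , drop = FALSE]
  if (is.null(end_time_s))
    end_time_s <- max(deltas$ectopic_time_s, na.rm = TRUE)
  if (!all(is.na(deltas$ectopic_time_s)))
    deltas <- deltas[is.na(deltas$ectopic_time_s) |
                       deltas$ectopic_time_s >= end_time_s - window_s, ,
                     drop = FALSE]
  deltas <- utils::tail(deltas, max_es)

  agg <- list(patient_id = patient_id, n_eligible = nrow(deltas))
  excluded <- character()
  for (v in names(.delta_vars)) {
    for (s in c("abs", "rel")) {
      col <- paste0("d", v, "_", s)
      vals <- deltas[[col]]
      vals <- vals[!is.na(vals)]
      agg[[col]] <- if (length(vals)) stats::median(vals) else NA_real_
    }
    bb <- deltas[[paste0("base_", v)]]
    bb <- bb[!is.na(bb)]
    agg[[paste0("base_", v)]] <- if (length(bb)) stats::median(bb) else NA_real_
    if (!length(bb)) excluded <- c(excluded, v)
  }
  cmp <- if (strict) `>` else `>=`
  if (!is.null(sv)) {
    stopifnot(inherits(sv, "sv_series"))
    dsv <- sv_response(sv)
    agg$sv_baseline_ml <- mean(sv$baseline_values)
    agg$sv_post_ml <- mean(sv$post_values)
    agg$dsv_rel_pct <- dsv
    agg$responder_10 <- cmp(dsv, 10)
    agg$responder_15 <- cmp(dsv, 15)
  } else {
    agg$sv_baseline_ml <- NA_real_
    agg$sv_post_ml <- NA_real_
    agg$dsv_rel_pct <- NA_real_
    agg$responder_10 <- NA
    agg$responder_15 <- NA
  }
  agg$excluded_vars <- paste(excluded, collapse = ",")
  structure(as.data.frame(agg, stringsAsFactors = FALSE),
            class = c("patient_summary", "data.frame"))
}

#' Compute per-ectopic deltas for a record's eligible extrasystoles
#'
#' Convenience bridge between [find_eligible_ectopics()] and
#' [post_ectopic_delta()]: for each eligible extrasystole, extracts its
#' ten-beat baseline and post-ectopic feature rows and computes the deltas.
#'
#' @param features A `beat_features` data frame ([features_for_record()]).
#' @param eligibles An `eligible_ectopics` data frame for the same record.
#' @return A data frame of [post_ectopic_delta()] rows (zero rows when
#'   `eligibles` is empty).
#' @export
deltas_for_record <- function(features, eligibles) {
  stopifnot(inherits(features, "beat_features"),
            inherits(eligibles, "eligible_ectopics"))
  rows <- lapply(seq_len(nrow(eligibles)), function(k) {
    e <- eligibles[k, ]
    post_ectopic_delta(features[e$baseline_start:e$baseline_end, ],
                       features[e$post_index, ],
                       ectopic_time_s = e$ectopic_time_s)
  })
  if (!length(rows)) {
    cols <- c("ectopic_time_s",
              as.vector(rbind(paste0("base_", names(.delta_vars)),
                              paste0("d", names(.delta_vars), "_abs"),
                              paste0("d", names(.delta_vars), "_rel"))))
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  do.call(rbind, rows)
}

#' Read / write patient summary tables
#'
#' The patient summary table (one row per patient, aggregated deltas plus
#' responder flags) is both the output of the waveform pipeline and the
#' native format of the cohort-tier simulator, making the two interchangeable
#' as input to the classification stage.
#'
#' @param path File path.
#' @return `read_patient_summaries()` returns a `patient_summary` data frame.
#' @export
read_patient_summaries <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"dsv_rel_pct" %in% names(dat))
    stop("not a patient summary table: missing dsv_rel_pct")
  for (fl in c("responder_10", "responder_15"))
    if (fl %in% names(dat)) dat[[fl]] <- as.logical(dat[[fl]])
  structure(dat, class = c("patient_summary", "data.frame"))
}

#' @rdname read_patient_summaries
#' @param summaries A `patient_summary` data frame.
#' @export
write_patient_summaries <- function(summaries, path) {
  utils::write.csv(as.data.frame(summaries), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
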