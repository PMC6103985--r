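#' Detect R-peaks in an ECG channel
#'
#' A Pan-Tompkins-style detector: band-pass filter (default 5-30 Hz),
#' differentiate, square, moving-window integrate, then pick integrated-energy
#' peaks above an adaptive threshold with a refractory period, and refine each
#' detection to the local ECG maximum. Works on either polarity via the
#' band-passed absolute amplitude at the refinement step.
#'
#' @param rec A [waveform_record()] at 1000 Hz (resample first with
#'   [resample_to_1khz()]); at least 2 s long.
#' @param refractory_ms Minimum distance between detections (ms).
#' @param band Band-pass corner frequencies in Hz, length 2.
#' @param threshold_frac Adaptive threshold as a fraction of the high quantile
#'   of integrated-energy peak heights.
#' @return A `beat_annotations` data frame with columns `r_index` (0-based
#'   sample index at 1 kHz), `r_time_s`, `label` (all `NA`; see
#'   [classify_beats()]), `rr_prev_ms` (`NA` for the first beat) and
#'   `coupling_ratio` (`NA`).
#' @export
detect_r_peaks <- function(rec, refractory_ms = 250, band = c(5, 30),
                           threshold_frac = 0.3) {
  stopifnot(inherits(rec, "waveform_record"))
  if (rec$fs != 1000) stop("detect_r_peaks expects a 1000 Hz record")
  n <- length(rec$ecg)
  if (rec$duration_s < 2) stop("record must be at least 2 s long")
  if (stats::sd(rec$ecg) < .Machine$double.eps^0.5)
    stop("no QRS energy: flat ECG channel")

  bf <- signal::butter(3, band / 500, type = "pass")
  bp <- signal::filtfilt(bf, rec$ecg - mean(rec$ecg))
  if (max(abs(bp)) < .Machine$double.eps^0.25)
    stop("no QRS energy: band-passed ECG is flat")

  d2 <- c(0, diff(bp))^2
  win <- 150L  # ms integration window
  integ <- as.numeric(stats::filter(d2, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0

  # local maxima of the integrated energy
  up <- diff(integ) > 0
  cand <- which(c(FALSE, up) & c(!up, FALSE))
  if (!length(cand)) stop("no QRS energy: no energy maxima found")
  thr <- threshold_frac * stats::quantile(integ[cand], 0.95, names = FALSE)
  cand <- cand[integ[cand] > thr]
  if (!length(cand)) stop("no QRS energy: all energy maxima below threshold")

  # enforce refractory period: keep the larger of peaks closer than refractory
  keep <- integer()
  for (i in cand) {
    if (length(keep) && (i - keep[length(keep)]) < refractory_ms) {
      if (integ[i] > integ[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }

  # refine: integrated peak lags the R wave; search band-passed |amplitude|
  # backwards, then snap to the raw ECG extremum
  r_idx <- vapply(keep, function(i) {
    lo <- max(1L, i - 120L); hi <- min(n, i + 40L)
    j <- lo - 1L + which.max(abs(bp[lo:hi]))
    lo2 <- max(1L, j - 15L); hi2 <- min(n, j + 15L)
    sgn <- sign(bp[j])
    if (sgn >= 0) lo2 - 1L + which.max(rec$ecg[lo2:hi2])
    else lo2 - 1L + which.min(rec$ecg[lo2:hi2])
  }, integer(1))
  r_idx <- sort(unique(r_idx))
  # refinement can re-merge neighbours; re-apply refractory on final indices
  if (length(r_idx) > 1L) {
    ok <- c(TRUE, diff(r_idx) >= refractory_ms)
    r_idx <- r_idx[ok]
  }

  beat_annotations(r_index = r_idx - 1L, fs = 1000)
}

#' Build a beat-annotation table from R-peak sample indices
#'
#' @param r_index Strictly increasing 0-based sample indices at `fs`.
#' @param fs Sampling rate (Hz).
#' @param label Optional character vector of labels
#'   (`sinus`, `ectopic`, `post_ectopic`, `artifact`).
#' @return A `beat_annotations` data frame (see [detect_r_peaks()]).
#' @export
beat_annotations <- function(r_index, fs = 1000, label = NA_character_) {
  r_index <- as.numeric(r_index)
  if (length(r_index) && any(diff(r_index) <= 0))
    stop("r_index must be strictly increasing")
  rr <- c(NA_real_, diff(r_index)) * 1000 / fs
  structure(
    data.frame(r_index = r_index,
               r_time_s = r_index / fs,
               label = rep_len(as.character(label), length(r_index)),
               rr_prev_ms = rr,
               coupling_ratio = NA_real_,
               stringsAsFactors = FALSE),
    class = c("beat_annotations", "data.frame"))
}

#' Classify beats as sinus, ectopic, post-ectopic or artifact
#'
#' A beat is labelled `ectopic` when its RR interval is at most
#' `coupling_max` (default 0.80, boundary inclusive) times the reference
#' sinus RR; the beat immediately following an ectopic is `post_ectopic`;
#' implausibly short RR intervals (<= 150 ms) and unexplained long pauses
#' (missed-beat gaps not preceded by an ectopic) are `artifact`; everything
#' else is `sinus`. The first 11 beats of a record are never labelled ectopic
#' (insufficient rhythm context). The reference interval is, by default, the
#' median RR of the up-to-10 most recent sinus beats (`coupling_ref =
#' "median10"`); `"last"` uses the single most recent sinus RR.
#'
#' @param beats A `beat_annotations` data frame ([detect_r_peaks()] or
#'   [beat_annotations()]); at least 12 beats.
#' @param coupling_max Prematurity threshold on the coupling ratio.
#' @param coupling_ref `"median10"` or `"last"`.
#' @param artifact_long_rr Pauses longer than this multiple of the reference
#'   RR, not following an ectopic, are flagged `artifact`.
#' @return The input with `label` filled in and `coupling_ratio` set on
#'   ectopic beats (RR / reference RR).
#' @export
classify_beats <- function(beats, coupling_max = 0.80,
                           coupling_ref = c("median10", "last"),
                           artifact_long_rr = 1.8) {
  stopifnot(inherits(beats, "beat_annotations"))
  coupling_ref <- match.arg(coupling_ref)
  n <- nrow(beats)
  if (n < 12L) stop("at least 12 beats are required to classify")
  lab <- rep("sinus", n)
  cr <- rep(NA_real_, n)
  sinus_rr <- numeric()  # rolling buffer of recent sinus RR intervals
  eps <- 1e-9
  for (i in seq_len(n)) {
    rr <- beats$rr_prev_ms[i]
    ref <- if (!length(sinus_rr)) NA_real_
           else if (coupling_ref == "median10") stats::median(utils::tail(sinus_rr, 10L))
           else utils::tail(sinus_rr, 1L)
    if (i == 1L || is.na(rr)) {
      lab[i] <- "sinus"
    } else if (rr <= 150) {
      lab[i] <- "artifact"
    } else if (i > 11L && !is.na(ref) && rr <= coupling_max * ref + eps) {
      lab[i] <- "ectopic"
      cr[i] <- rr / ref
    } else if (lab[i - 1L] == "ectopic") {
      lab[i] <- "post_ectopic"
    } else if (!is.na(ref) && lab[i - 1L] != "artifact" &&
               rr > artifact_long_rr * ref) {
      lab[i] <- "artifact"
    } else {
      lab[i] <- "sinus"
    }
    if (lab[i] == "sinus" && !is.na(rr) && lab[i - 1L] == "sinus")
      sinus_rr <- c(sinus_rr, rr)
  }
  beats$label <- lab
  beats$coupling_ratio <- cr
  beats
}

#' Find eligible extrasystoles
#'
#' Applies the eligibility rules for post-ectopic analysis: an ectopic beat
#' qualifies when (i) the ten beats immediately preceding it are all
#' sinus-labelled, (ii) its coupling interval is at most `coupling_max`
#' (default 80 percent, inclusive) of the median RR of those ten baseline
#' beats, (iii) the next beat exists and is the post-ectopic beat, and
#' (iv) it falls inside the lookback window (default 30 min) ending at the
#' last annotated beat.
#'
#' @param beats A labelled `beat_annotations` data frame
#'   (see [classify_beats()]).
#' @param window_s Lookback window in seconds before the record end.
#' @param coupling_max Eligibility threshold on the coupling ratio.
#' @return An `eligible_ectopics` data frame, time-ordered, with columns
#'   `ectopic_index`, `post_index`, `baseline_start`, `baseline_end`
#'   (1-based row numbers into `beats`), `ectopic_time_s`, `coupling_ratio`
#'   and `pause_ratio` (post-ectopic RR / baseline median RR). Zero rows when
#'   no ectopic qualifies (the method is then not applicable).
#' @export
find_eligible_ectopics <- function(beats, window_s = 1800, coupling_max = 0.80) {
  stopifnot(inherits(beats, "beat_annotations"))
  if (is.na(window_s) || window_s <= 0) stop("window_s must be positive")
  n <- nrow(beats)
  empty <- structure(
    data.frame(ectopic_index = integer(), post_index = integer(),
               baseline_start = integer(), baseline_end = integer(),
               ectopic_time_s = numeric(), coupling_ratio = numeric(),
               pause_ratio = numeric()),
    class = c("eligible_ectopics", "data.frame"))
  ect <- which(beats$label == "ectopic")
  if (!length(ect)) return(empty)
  t_end <- beats$r_time_s[n]
  eps <- 1e-9
  rows <- lapply(ect, function(i) {
    if (i < 12L || i + 1L > n) return(NULL)
    base <- (i - 10L):(i - 1L)
    if (!all(beats$label[base] == "sinus")) return(NULL)
    if (beats$label[i + 1L] != "post_ectopic") return(NULL)
    ref <- stats::median(beats$rr_prev_ms[base])
    if (is.na(ref) || ref <= 0) return(NULL)
    cr <- beats$rr_prev_ms[i] / ref
    if (cr > coupling_max + eps) return(NULL)
    if (beats$r_time_s[i] < t_end - window_s) return(NULL)
    data.frame(ectopic_index = i, post_index = i + 1L,
               baseline_start = i - 10L, baseline_end = i - 1L,
               ectopic_time_s = beats$r_time_s[i],
               coupling_ratio = cr,
               pause_ratio = beats$rr_prev_ms[i + 1L] / ref)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  structure(out[order(out$ectopic_time_s), , drop = FALSE],
            class = c("eligible_ectopics", "data.frame"))
}

#' Write beat annotations to delimited text
#'
#' @param beats A `beat_annotations` data frame.
#' @param path Output path.
#' @param patient_id Patient identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_beat_annotations <- function(beats, path, patient_id = "unknown") {
  stopifnot(inherits(beats, "beat_annotations"))
  out <- cbind(patient_id = patient_id, as.data.frame(beats))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
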