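#' Delineate one arterial pulse and derive per-beat pressure variables
#'
#' Locates the pulse onset ("foot") after an R-peak by the
#' intersecting-tangent method: the tangent at the point of maximal systolic
#' upstroke slope is intersected with the horizontal line through the
#' preceding pressure minimum. From the foot, the beat's systolic pressure
#' (SBP), diastolic pressure (DBP, pressure at the foot level), pulse
#' pressure (PP = SBP - DBP), maximal upstroke slope (dP/dt max, mmHg/ms)
#' and pre-ejection period (PEP, R-peak to foot, ms; includes vascular
#' transit time) are derived. The derivative is taken with a zero-phase
#' Savitzky-Golay differentiator over a 25 ms window, so staircase artifacts
#' from upsampled signals do not dominate dP/dt.
#'
#' Validity is tracked per variable: a waveform clipped ("cut") near the
#' diastolic level invalidates foot-dependent variables (PEP, PP, DBP,
#' dP/dt) but leaves SBP usable; an absent upstroke invalidates everything.
#'
#' @param abp Full-record ABP vector at 1000 Hz (mmHg).
#' @param r_index 0-based sample index of the beat's R-peak.
#' @param next_r 0-based sample index of the next R-peak (or the last sample
#'   for the final beat); must exceed `r_index`.
#' @param foot_window_ms Foot search window after the R-peak.
#' @param peak_window_ms Systolic-peak search window after the foot.
#' @param min_slope Minimal acceptable upstroke slope (mmHg/ms) below which
#'   the beat is flagged "no upstroke".
#' @param clip_frac Fraction of beat samples lying at the segment minimum
#'   above which the beat is flagged "waveform cut".
#' @return A one-row data frame: `foot_index` (0-based), `sbp_mmHg`,
#'   `dbp_mmHg`, `pp_mmHg`, `map_mmHg` (`NA` here; filled by
#'   [features_for_record()]), `dpdt_max`, `pep_ms`, per-variable validity
#'   flags `valid_sbp`, `valid_pep`, `valid_pp`, `valid_dpdt`, an overall
#'   `valid` flag and a `reason` string when invalid.
#' @export
delineate_beat <- function(abp, r_index, next_r,
                           foot_window_ms = 400, peak_window_ms = 350,
                           min_slope = 0.08, clip_frac = 0.05) {
  n <- length(abp)
  i0 <- as.integer(round(r_index)) + 1L   # 1-based R sample
  i1 <- as.integer(round(next_r)) + 1L
  if (i0 < 1L || i1 > n || i1 <= i0)
    stop("malformed beat indices: r_index=", r_index, ", next_r=", next_r)

  invalid <- function(reason, sbp = NA_real_, valid_sbp = FALSE) {
    data.frame(foot_index = NA_real_, sbp_mmHg = sbp, dbp_mmHg = NA_real_,
               pp_mmHg = NA_real_, map_mmHg = NA_real_, dpdt_max = NA_real_,
               pep_ms = NA_real_, valid_sbp = valid_sbp, valid_pep = FALSE,
               valid_pp = FALSE, valid_dpdt = FALSE, valid = FALSE,
               reason = reason, stringsAsFactors = FALSE)
  }

  seg_all <- abp[i0:i1]
  # clipping QC: a run of samples pinned at the beat minimum means the
  # waveform was cut near the diastolic level
  if (mean(abs(seg_all - min(seg_all)) < 1e-9) > clip_frac) {
    sbp_guess <- max(seg_all)
    return(invalid("waveform cut", sbp = sbp_guess,
                   valid_sbp = (max(seg_all) - min(seg_all)) > 5))
  }

  hi_search <- min(i0 + foot_window_ms, i1, n)
  if (hi_search - i0 < 30L) return(invalid("beat too short"))
  win <- i0:hi_search
  if (max(abp[win]) - min(abp[win]) < 1) return(invalid("no upstroke"))

  # smoothed derivative (mmHg/ms at 1 kHz) over the beat neighbourhood
  lo_d <- max(1L, i0 - 50L); hi_d <- min(n, i1 + 50L)
  d <- signal::sgolayfilt(abp[lo_d:hi_d], p = 3, n = 25, m = 1)
  dwin <- d[win - lo_d + 1L]
  ms_rel <- which.max(dwin)
  ms_idx <- win[ms_rel]
  if (!is.finite(dwin[ms_rel]) || dwin[ms_rel] < min_slope)
    return(invalid("no upstroke"))

  # preceding pressure minimum between the R-peak and the max-slope point
  pre <- i0:ms_idx
  pmin_val <- min(abp[pre])

  # tangent slope and anchor by least squares over the central (25-75 %)
  # portion of the upstroke: unbiased under additive noise, unlike the
  # single maximum of the (noisy) derivative
  pk <- max(abp[ms_idx:min(ms_idx + 150L, n)])
  lo_p <- pmin_val + 0.25 * (pk - pmin_val)
  hi_p <- pmin_val + 0.75 * (pk - pmin_val)
  rise <- ms_rel
  while (rise[1L] > 1L && abp[win[rise[1L] - 1L]] >= lo_p)
    rise <- c(rise[1L] - 1L, rise)
  while (rise[length(rise)] < length(win) &&
         abp[win[rise[length(rise)] + 1L]] <= hi_p)
    rise <- c(rise, rise[length(rise)] + 1L)
  ri <- win[rise]
  if (length(ri) >= 3L) {
    slope <- stats::cov(ri, abp[ri]) / stats::var(ri)
    anchor_i <- mean(ri); anchor_p <- mean(abp[ri])
  } else {
    slope <- dwin[ms_rel]
    anchor_i <- ms_idx; anchor_p <- abp[ms_idx]
  }
  if (!is.finite(slope) || slope < min_slope) return(invalid("no upstroke"))
  # intersecting tangent: foot where the tangent reaches the minimum level
  foot_f <- anchor_i - (anchor_p - pmin_val) / slope   # fractional sample
  if (!is.finite(foot_f) || foot_f <= i0) return(invalid("foot before R"))
  foot_i <- as.integer(round(foot_f))
  pep_ms <- foot_f - i0

  hi_peak <- min(foot_i + peak_window_ms, i1, n)
  sys <- foot_i:hi_peak
  sbp_rel <- which.max(abp[sys])
  sbp <- abp[sys[sbp_rel]]
  sbp_idx <- sys[sbp_rel]
  dbp <- pmin_val
  if (sbp <= dbp) return(invalid("no systolic peak", sbp = sbp))

  dpdt <- max(d[(foot_i:sbp_idx) - lo_d + 1L])

  data.frame(foot_index = foot_f - 1,  # 0-based, fractional
             sbp_mmHg = sbp, dbp_mmHg = dbp, pp_mmHg = sbp - dbp,
             map_mmHg = NA_real_, dpdt_max = dpdt, pep_ms = pep_ms,
             valid_sbp = TRUE, valid_pep = TRUE, valid_pp = TRUE,
             valid_dpdt = TRUE, valid = TRUE, reason = "",
             stringsAsFactors = FALSE)
}

#' Per-beat pressure features for a whole record
#'
#' Runs [delineate_beat()] for every annotated beat (including ectopic beats,
#' whose features are kept for QC but excluded from delta computation
#' downstream) and fills in per-beat mean arterial pressure (MAP) as the mean
#' ABP between consecutive pulse feet.
#'
#' @param rec A [waveform_record()] at 1000 Hz.
#' @param beats A labelled `beat_annotations` data frame from the same record.
#' @param ... Passed to [delineate_beat()].
#' @return A `beat_features` data frame: one row per beat, the annotation
#'   columns (`r_index`, `r_time_s`, `label`, `rr_prev_ms`) followed by the
#'   [delineate_beat()] columns.
#' @export
features_for_record <- function(rec, beats, ...) {
  stopifnot(inherits(rec, "waveform_record"), inherits(beats, "beat_annotations"))
  if (rec$fs != 1000) stop("features_for_record expects a 1000 Hz record")
  n <- length(rec$abp)
  nb <- nrow(beats)
  if (nb < 1L) stop("no beats to delineate")
  if (max(beats$r_index) >= n)
    stop("record/beat mismatch: annotation beyond record end")
  next_r <- c(beats$r_index[-1L], n - 1L)
  feats <- do.call(rbind, lapply(seq_len(nb), function(i) {
    delineate_beat(rec$abp, beats$r_index[i], next_r[i], ...)
  }))
  # MAP over [foot_i, foot_{i+1})
  foot1 <- round(feats$foot_index) + 1L  # 1-based
  for (i in seq_len(nb)) {
    if (is.na(foot1[i])) next
    hi <- if (i < nb && !is.na(foot1[i + 1L])) foot1[i + 1L] - 1L
          else min(n, foot1[i] + 1000L)
    if (hi > foot1[i]) feats$map_mmHg[i] <- mean(rec$abp[foot1[i]:hi])
  }
  out <- cbind(beats[, c("r_index", "r_time_s", "label", "rr_prev_ms")], feats)
  structure(out, class = c("beat_features", "data.frame"))
}
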