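#' Construct a two-channel waveform record
#'
#' A `waveform_record` holds paired, uniformly sampled ECG and invasive
#' arterial blood pressure (ABP) signals for one patient. Both channels must
#' have identical length and contain no missing samples; gaps must be handled
#' upstream (records with `NA`s are rejected).
#'
#' @param ecg Numeric vector of ECG samples (millivolt-scale; units are not
#'   interpreted by the pipeline).
#' @param abp Numeric vector of arterial pressure samples (mmHg), same length
#'   as `ecg`.
#' @param fs Sampling rate in Hz (> 0).
#' @param patient_id Patient identifier (single string).
#' @param t_start Time offset of the first sample in seconds.
#'
#' @return An object of class `waveform_record`: a list with elements
#'   `patient_id`, `fs`, `t_start`, `ecg`, `abp` and `duration_s`
#'   (equal to `(n - 1) / fs`).
#' @export
#' @examples
#' rec <- waveform_record(ecg = sin(1:100), abp = 80 + 10 * sin(1:100),
#'                        fs = 125, patient_id = "P01")
#' rec$duration_s
waveform_record <- function(ecg, abp, fs, patient_id = "unknown", t_start = 0) {
  ecg <- as.numeric(ecg)
  abp <- as.numeric(abp)
  if (length(ecg) < 1L || length(ecg) != length(abp))
    stop("ecg and abp must have identical length >= 1")
  if (anyNA(ecg) || anyNA(abp))
    stop("waveform contains missing samples; records with gaps are rejected")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  structure(
    list(patient_id = as.character(patient_id)[1L],
         fs = as.numeric(fs),
         t_start = as.numeric(t_start)[1L],
         ecg = ecg, abp = abp,
         duration_s = (length(ecg) - 1L) / fs),
    class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> patient %s: %d samples @ %g Hz (%.3f s)\n",
              x$patient_id, length(x$ecg), x$fs, x$duration_s))
  invisible(x)
}

#' Time axis of a waveform record
#'
#' @param rec A [waveform_record()].
#' @return Numeric vector of sample times in seconds
#'   (`t_start + (0:(n-1))/fs`).
#' @export
waveform_time <- function(rec) {
  stopifnot(inherits(rec, "waveform_record"))
  rec$t_start + (seq_along(rec$ecg) - 1L) / rec$fs
}

# parse "# key=value" metadata lines at the top of a waveform file
parse_waveform_header <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      meta[[key]] <- val
    }
  }
  meta
}

#' Read a waveform file
#'
#' Reads a delimited-text waveform file: optional `# key=value` metadata lines
#' (`fs`, `patient_id`, `t_start`), then a `time,ecg,abp` header and one
#' comma-separated row per sample. Channel order in the file is free; columns
#' are matched by name and normalised to (ecg, abp). The time column must be
#' uniform and consistent with the declared sampling rate; when no `fs`
#' metadata is present the rate is inferred from the time column.
#'
#' @param path Path to the file.
#' @return A validated [waveform_record()].
#' @seealso [write_waveform()]
#' @export
read_waveform <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta <- parse_waveform_header(lines[is_meta])
  body <- lines[!is_meta]
  if (length(body) < 2L)
    stop("format error in ", path, ": no data rows")
  header <- tolower(trimws(strsplit(body[1L], ",", fixed = TRUE)[[1L]]))
  need <- c("time", "ecg", "abp")
  missing_col <- setdiff(need, header)
  if (length(missing_col))
    stop("format error in ", path, ": missing channel/column '",
         paste(missing_col, collapse = "', '"), "' (line 1 of data header)")
  dat <- utils::read.csv(textConnection(body[-1L]), header = FALSE,
                         col.names = header, colClasses = "character")
  names(dat) <- header
  # line number (within the full file) of each data row, for error messages
  data_line_no <- which(!is_meta)[-1L]
  num <- lapply(dat[need], function(col) suppressWarnings(as.numeric(col)))
  for (v in need) {
    bad <- which(is.na(num[[v]]))
    if (length(bad))
      stop("format error in ", path, ": non-numeric or missing '", v,
           "' sample at line ", data_line_no[bad[1L]])
  }
  tm <- num$time
  fs <- if (!is.null(meta$fs)) as.numeric(meta$fs) else NA_real_
  if (length(tm) > 1L) {
    dt <- diff(tm)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
      bad <- which(abs(dt - stats::median(dt)) > 1e-6 * stats::median(dt))[1L]
      stop("format error in ", path, ": non-uniform time column at line ",
           data_line_no[bad + 1L])
    }
    fs_obs <- 1 / stats::median(dt)
    if (is.na(fs)) fs <- fs_obs
    else if (abs(fs_obs - fs) > 1e-3 * fs)
      stop("format error in ", path, ": time column step inconsistent with fs=", fs)
  }
  if (is.na(fs)) stop("format error in ", path, ": sampling rate undeclared")
  waveform_record(ecg = num$ecg, abp = num$abp, fs = fs,
                  patient_id = if (!is.null(meta$patient_id)) meta$patient_id else "unknown",
                  t_start = if (length(tm)) tm[1L] else 0)
}

#' Write a waveform record to a delimited-text file
#'
#' @param rec A [waveform_record()].
#' @param path Output path.
#' @param digits Number of significant decimal digits for samples.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(rec, path, digits = 6) {
  stopifnot(inherits(rec, "waveform_record"))
  tm <- waveform_time(rec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# postectopic waveform v1",
               paste0("# patient_id=", rec$patient_id),
               paste0("# fs=", format(rec$fs, digits = 12)),
               paste0("# t_start=", format(rec$t_start, digits = 12)),
               "time,ecg,abp"), con)
  writeLines(paste(formatC(tm, format = "f", digits = 6),
                   formatC(rec$ecg, format = "f", digits = digits),
                   formatC(rec$abp, format = "f", digits = digits),
                   sep = ","), con)
  invisible(path)
}

#' Resample a waveform record to 1 kHz
#'
#' Upsamples both channels to a 1 ms grid running from 0 to the record
#' duration by cubic-spline interpolation (the same scheme for ECG and ABP).
#' Input samples are reproduced exactly at coincident grid points and the
#' spline is only evaluated inside the sampled range (no extrapolation).
#' A record already at 1000 Hz is returned unchanged.
#'
#' @param rec A [waveform_record()] with `fs <= 1000`.
#' @return A [waveform_record()] at 1000 Hz.
#' @export
resample_to_1khz <- function(rec) {
  stopifnot(inherits(rec, "waveform_record"))
  if (rec$fs > 1000)
    stop("fs > 1000 Hz unsupported: downsampling is out of scope")
  if (rec$fs == 1000) return(rec)
  n <- length(rec$ecg)
  t_in <- (seq_len(n) - 1L) / rec$fs
  t_out <- seq(0, t_in[n], by = 1e-3)
  if (n == 1L) t_out <- 0
  interp <- function(y) {
    if (n < 4L) return(stats::approx(t_in, y, xout = t_out, rule = 2)$y)
    stats::spline(t_in, y, xout = t_out, method = "fmm")$y
  }
  waveform_record(ecg = interp(rec$ecg), abp = interp(rec$abp), fs = 1000,
                  patient_id = rec$patient_id, t_start = rec$t_start)
}

#' Construct a stroke-volume series
#'
#' Stroke-volume (SV) readings from the 5-minute windows immediately before
#' and after a fluid bolus. The reference protocol averages ten consecutive
#' readings per window; any count >= 1 is accepted and a QC note is attached
#' when a window does not hold ten readings.
#'
#' @param patient_id Patient identifier.
#' @param baseline_values Numeric vector (> 0) of pre-fluid SV readings (ml).
#' @param post_values Numeric vector (> 0) of post-fluid SV readings (ml).
#' @return An object of class `sv_series` with a `qc` attribute
#'   (character vector of notes, possibly empty).
#' @export
sv_series <- function(patient_id, baseline_values, post_values) {
  baseline_values <- as.numeric(baseline_values)
  post_values <- as.numeric(post_values)
  if (!length(baseline_values) || !length(post_values))
    stop("both SV windows must contain at least one reading")
  if (anyNA(baseline_values) || anyNA(post_values) ||
      any(baseline_values <= 0) || any(post_values <= 0))
    stop("all SV values must be positive")
  qc <- character()
  if (length(baseline_values) != 10L)
    qc <- c(qc, sprintf("baseline window has %d readings (expected 10)",
                        length(baseline_values)))
  if (length(post_values) != 10L)
    qc <- c(qc, sprintf("post window has %d readings (expected 10)",
                        length(post_values)))
  structure(list(patient_id = as.character(patient_id)[1L],
                 baseline_values = baseline_values,
                 post_values = post_values),
            qc = qc, class = "sv_series")
}

#' Relative stroke-volume change after fluid infusion
#'
#' @param sv An [sv_series()].
#' @return Relative SV change in percent:
#'   `100 * (mean(post) - mean(baseline)) / mean(baseline)`.
#' @export
#' @examples
#' sv <- sv_series("P01", rep(70, 10), rep(77, 10))
#' sv_response(sv)  # +10
sv_response <- function(sv) {
  stopifnot(inherits(sv, "sv_series"))
  b <- mean(sv$baseline_values)
  100 * (mean(sv$post_values) - b) / b
}

#' Read a stroke-volume table
#'
#' Expects delimited text with columns `patient_id,window,sv_ml`, where
#' `window` is `baseline` or `post`.
#'
#' @param path Path to the file.
#' @return A named list of [sv_series()], one element per patient.
#' @export
read_sv_table <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("patient_id", "window", "sv_ml")
  if (!all(need %in% names(dat)))
    stop("SV table must have columns ", paste(need, collapse = ","))
  if (!all(dat$window %in% c("baseline", "post")))
    stop("SV table 'window' must be 'baseline' or 'post'")
  out <- lapply(split(dat, dat$patient_id), function(d) {
    sv_series(d$patient_id[1L],
              d$sv_ml[d$window == "baseline"],
              d$sv_ml[d$window == "post"])
  })
  out
}

#' Write a stroke-volume table
#'
#' @param sv_list A list of [sv_series()] (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_table <- function(sv_list, path) {
  if (inherits(sv_list, "sv_series")) sv_list <- list(sv_list)
  rows <- do.call(rbind, lapply(sv_list, function(sv) {
    rbind(data.frame(patient_id = sv$patient_id, window = "baseline",
                     sv_ml = sv$baseline_values),
          data.frame(patient_id = sv$patient_id, window = "post",
                     sv_ml = sv$post_values))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
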