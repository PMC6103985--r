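# shared fixtures and independent oracles for the test suite

# beat annotations from a vector of RR intervals (ms); first beat at sample 0
rr_beats <- function(rr_ms, fs = 1000) {
  beat_annotations(r_index = cumsum(c(0, rr_ms)) * fs / 1000, fs = fs)
}

# brute-force ROC area: exhaustive pairwise comparison, ties counted one half
brute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  x <- scores[labels]; y <- scores[!labels]
  tot <- 0
  for (xi in x) for (yj in y)
    tot <- tot + (xi > yj) + 0.5 * (xi == yj)
  tot / (length(x) * length(y))
}

# one programmed arterial pulse: slowly decaying diastole, linear upstroke
# from the foot, then a linear systolic decay -- every landmark is known
synth_pulse <- function(n = 1500, foot = 313, rise = 100,
                        dbp = 60, sbp = 120, tail_end = 80) {
  abp <- numeric(n)
  pre <- seq_len(foot)
  abp[pre] <- dbp + 2 * (foot - pre) / (foot - 1)         # 62 -> dbp at foot
  up <- seq_len(rise)
  abp[foot + up] <- dbp + (sbp - dbp) * up / rise
  pk <- foot + rise
  dec <- (pk + 1L):n
  abp[dec] <- sbp - (sbp - tail_end) * (dec - pk) / (n - pk)
  abp
}

# minimal beat-feature rows for delta tests
feat_row <- function(sbp = 120, pep = 212, pp = 60, dpdt = 0.9) {
  data.frame(sbp_mmHg = sbp, pep_ms = pep, pp_mmHg = pp, dpdt_max = dpdt,
             valid_sbp = TRUE, valid_pep = TRUE, valid_pp = TRUE,
             valid_dpdt = TRUE)
}
feat_rows <- function(n, ...) {
  row <- feat_row(...)
  out <- row[rep(1L, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ground-truth per-patient aggregate from a simulator truth table: median,
# over the <= max_es most recent eligible extrasystoles, of (post-ectopic
# value - median of the 10 preceding sinus values)
gt_aggregate <- function(truth, col = "sbp_mmHg", max_es = 10L) {
  idx <- which(truth$eligible)
  if (!length(idx)) return(NA_real_)
  idx <- utils::tail(idx, max_es)
  d <- vapply(idx, function(i) {
    truth[[col]][i + 1L] - stats::median(truth[[col]][(i - 10L):(i - 1L)])
  }, numeric(1))
  stats::median(d)
}
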