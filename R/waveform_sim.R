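#' Cohort-tier simulation configuration
#'
#' Parameters for drawing per-patient aggregated post-ectopic deltas
#' directly at the cohort level. Defaults reproduce the group structure of
#' the reference ICU cohort: 20 non-responders and 6 responders, with the
#' absolute post-ectopic changes and sinus-beat baselines of each variable
#' normally distributed within group (mean, SD):
#' SBP change -0.1 (5.6) vs 5.9 (6.6) mmHg; PEP change 4.0 (5.3) vs
#' 7.5 (2.9) ms; PP change 4.0 (6.7) vs 10.6 (7.0) mmHg; dP/dt change
#' 0.08 (0.11) vs 0.16 (0.08) mmHg/ms. Relative SV changes are uniform
#' within -8 to 8 % (non-responders) and 10 to 30 % (responders).
#'
#' @param n_nonresp,n_resp Group sizes.
#' @param deltas_abs Named list (`sbp`, `pep`, `pp`, `dpdt`) of numeric
#'   vectors `c(mu_nonresp, sd_nonresp, mu_resp, sd_resp)` for the absolute
#'   deltas.
#' @param baselines Same structure for the sinus-beat baseline values.
#' @param dsv_nonresp,dsv_resp Ranges (%) for the uniform relative SV change
#'   per group.
#' @param seed Optional integer seed.
#' @return A validated list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_nonresp = 20L, n_resp = 6L,
                              deltas_abs = list(sbp = c(-0.1, 5.6, 5.9, 6.6),
                                                pep = c(4.0, 5.3, 7.5, 2.9),
                                                pp = c(4.0, 6.7, 10.6, 7.0),
                                                dpdt = c(0.08, 0.11, 0.16, 0.08)),
                              baselines = list(sbp = c(116, 21, 125, 35),
                                               pep = c(212, 39, 212, 34),
                                               pp = c(58, 21, 65, 22),
                                               dpdt = c(0.88, 0.47, 0.94, 0.39)),
                              dsv_nonresp = c(-8, 8), dsv_resp = c(10, 30),
                              seed = NULL) {
  if (n_nonresp < 0L || n_resp < 0L || (n_nonresp + n_resp) < 1L)
    stop("group sizes must be non-negative with at least one patient")
  for (nm in names(.delta_vars)) {
    for (lst in list(deltas_abs, baselines)) {
      p <- lst[[nm]]
      if (is.null(p) || length(p) != 4L || any(!is.finite(p)) ||
          any(p[c(2L, 4L)] <= 0))
        stop("invalid parameters for variable '", nm,
             "': need c(mu_nonresp, sd_nonresp, mu_resp, sd_resp) with SDs > 0")
    }
  }
  structure(list(n_nonresp = as.integer(n_nonresp),
                 n_resp = as.integer(n_resp),
                 deltas_abs = deltas_abs, baselines = baselines,
                 dsv_nonresp = sort(dsv_nonresp), dsv_resp = sort(dsv_resp),
                 seed = seed),
            class = "cohort_sim_config")
}

#' Simulate cohort-level patient summaries
#'
#' Draws a patient-summary table with the statistical structure of the
#' reference cohort: within each response group, each variable's aggregated
#' absolute post-ectopic delta and baseline are drawn from the configured
#' normal distributions; the relative delta is derived as
#' `100 * delta_abs / baseline`; the relative SV change is uniform within
#' the group's range. Baselines are redrawn while below 20 % of the group
#' mean so relative deltas stay finite. The output has the same schema as
#' the waveform pipeline's patient summaries.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A `patient_summary` data frame with `n_nonresp + n_resp` rows and
#'   an attribute `truth` (the configuration and the group assignment).
#' @export
simulate_cohort_summaries <- function(cfg = cohort_sim_config()) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_nonresp + cfg$n_resp
  resp <- rep(c(FALSE, TRUE), c(cfg$n_nonresp, cfg$n_resp))
  out <- data.frame(patient_id = sprintf("SIM%03d", seq_len(n)),
                    n_eligible = sample.int(10L, n, replace = TRUE),
                    stringsAsFactors = FALSE)
  draw <- function(par, grp) stats::rnorm(length(grp),
                                          ifelse(grp, par[3L], par[1L]),
                                          ifelse(grp, par[4L], par[2L]))
  for (v in names(.delta_vars)) {
    dabs <- draw(cfg$deltas_abs[[v]], resp)
    base <- draw(cfg$baselines[[v]], resp)
    mu <- ifelse(resp, cfg$baselines[[v]][3L], cfg$baselines[[v]][1L])
    bad <- which(base < 0.2 * mu)
    while (length(bad)) {
      base[bad] <- draw(cfg$baselines[[v]], resp)[bad]
      bad <- which(base < 0.2 * mu)
    }
    out[[paste0("base_", v)]] <- base
    out[[paste0("d", v, "_abs")]] <- dabs
    out[[paste0("d", v, "_rel")]] <- 100 * dabs / base
  }
  dsv <- ifelse(resp,
                stats::runif(n, cfg$dsv_resp[1L], cfg$dsv_resp[2L]),
                stats::runif(n, cfg$dsv_nonresp[1L], cfg$dsv_nonresp[2L]))
  out$sv_baseline_ml <- stats::rnorm(n, 72, 23)
  out$sv_baseline_ml[out$sv_baseline_ml < 20] <- 20
  out$sv_post_ml <- out$sv_baseline_ml * (1 + dsv / 100)
  out$dsv_rel_pct <- dsv
  out$responder_10 <- dsv >= 10
  out$responder_15 <- dsv >= 15
  out$excluded_vars <- ""
  attr(out, "truth") <- list(config = cfg, responder = resp)
  structure(out, class = c("patient_summary", "data.frame"))
}

#' Logistic Frank-Starling stroke-volume surrogate
#'
#' `SV = sv_max / (1 + exp(-(preload - p50) / slope_k))`: monotone
#' non-decreasing in preload, steep around `p50` and flat (plateau,
#' non-responder regime) far above it. Preload is in arbitrary units.
#'
#' @param preload Preload (arbitrary units), vectorised.
#' @param sv_max_ml Plateau stroke volume (ml).
#' @param p50 Preload at half-maximal SV.
#' @param slope_k Steepness scale (larger is flatter).
#' @return Stroke volume in ml.
#' @export
#' @examples
#' starling_sv(0, sv_max_ml = 100, p50 = 0, slope_k = 0.7)  # 50
starling_sv <- function(preload, sv_max_ml = 100, p50 = 0, slope_k = 0.7) {
  stopifnot(sv_max_ml > 0, slope_k > 0)
  sv_max_ml / (1 + exp(-(preload - p50) / slope_k))
}

#' Patient-tier (beat-resolved) simulation configuration
#'
#' Parameters for generating raw two-channel ECG/ABP waveforms with sinus
#' rhythm, respiratory RR modulation, premature beats with compensatory
#' pauses, preload-dependent hemodynamics and ground-truth annotations.
#' Mechanism (all functional forms are this package's inventions, chosen to
#' emulate the narrative physiology): per-beat preload grows with filling
#' time (previous RR relative to nominal) plus a residual-volume bonus after
#' the ectopic's poor ejection; stroke volume follows the logistic
#' Frank-Starling surrogate; pulse pressure is SV over arterial compliance;
#' diastole decays exponentially (windkessel) toward `p_inf_mmHg`; the ABP
#' onset lags each R-peak by a preload-dependent pre-ejection period
#' (negative `pep_preload_coef_ms` makes post-ectopic PEP increase).
#' Ventricular ectopics get a full compensatory pause (pre- plus
#' post-ectopic interval = 2 x local RR); supraventricular ectopics reset
#' the sinus node (partial pause).
#'
#' The default operating point sits on the steep Starling portion (a fluid
#' responder); see [sim_nonresponder_config()] for the plateau regime.
#'
#' @param duration_s Record length (s).
#' @param hr_bpm Mean sinus heart rate.
#' @param rr_sd_ms Gaussian RR jitter SD (ms).
#' @param resp_rate_hz Respiratory rate (Hz).
#' @param resp_rr_mod_ms Amplitude of sinusoidal respiratory RR modulation (ms).
#' @param p_ectopic Per-beat probability of inserting an extrasystole.
#' @param coupling_range Coupling interval as a fraction of the local RR.
#' @param es_type_mix Fraction of ectopics that are ventricular.
#' @param sv_max_ml,p50,slope_k Starling surrogate parameters.
#' @param operating_point Baseline preload (arbitrary units).
#' @param preload_gain Preload units per unit fractional filling-time change.
#' @param resid_bonus Preload bonus at the post-ectopic beat from the
#'   ectopic's poor ejection.
#' @param compliance_ml_per_mmHg Arterial compliance (PP = SV / compliance).
#' @param tau_windkessel_s Diastolic decay time constant (s).
#' @param p_inf_mmHg Asymptotic decay pressure (mmHg).
#' @param pep0_ms Baseline pre-ejection period including vascular transit
#'   time (ms).
#' @param pep_preload_coef_ms PEP change per preload unit; negative values
#'   make PEP rise with preload.
#' @param pep_noise_sd_ms Beat-to-beat PEP noise SD (ms).
#' @param ecg_noise_sd Additive ECG noise SD (R amplitude is 1).
#' @param abp_noise_sd_mmHg Additive ABP noise SD (mmHg).
#' @param sv_noise_sd_ml Reading noise of the SV monitor (ml).
#' @param fluid_bolus_preload_shift Preload shift of the 500 ml bolus.
#' @param fs Output sampling rate (Hz); 125 by default so the pipeline's own
#'   resampling path is always exercised.
#' @param seed Optional integer seed.
#' @return A validated list of class `patient_sim_config`.
#' @export
patient_sim_config <- function(duration_s = 1800, hr_bpm = 75, rr_sd_ms = 20,
                               resp_rate_hz = 0.25, resp_rr_mod_ms = 25,
                               p_ectopic = 0.01,
                               coupling_range = c(0.5, 0.8),
                               es_type_mix = 0.5,
                               sv_max_ml = 100, p50 = 0, slope_k = 0.7,
                               operating_point = 0.66,
                               preload_gain = 0.5, resid_bonus = 0.35,
                               compliance_ml_per_mmHg = 1.24,
                               tau_windkessel_s = 0.8, p_inf_mmHg = 25,
                               pep0_ms = 212, pep_preload_coef_ms = -10,
                               pep_noise_sd_ms = 1.5,
                               ecg_noise_sd = 0.01, abp_noise_sd_mmHg = 0.3,
                               sv_noise_sd_ml = 2,
                               fluid_bolus_preload_shift = 0.5,
                               fs = 125, seed = NULL) {
  if (duration_s <= 10 || hr_bpm <= 0 || rr_sd_ms < 0 || resp_rate_hz <= 0 ||
      fs <= 0 || tau_windkessel_s <= 0 || compliance_ml_per_mmHg <= 0)
    stop("all rates and periods must be positive")
  if (p_ectopic < 0 || p_ectopic > 0.2)
    stop("p_ectopic must be in [0, 0.2]")
  if (length(coupling_range) != 2L || coupling_range[1L] <= 0 ||
      coupling_range[2L] > 0.8 || diff(coupling_range) < 0)
    stop("coupling_range must lie within (0, 0.8]")
  rr0 <- 60000 / hr_bpm
  if (rr0 * coupling_range[1L] < 300 || rr0 - 3 * rr_sd_ms - resp_rr_mod_ms < 300)
    stop("configuration yields RR intervals below 300 ms")
  args <- as.list(environment())
  args$rr0 <- NULL
  structure(args, class = "patient_sim_config")
}

#' Non-responder flavour of the patient simulation configuration
#'
#' Same mechanism as [patient_sim_config()] but operating on the Starling
#' plateau: a preload shift barely changes stroke volume.
#'
#' @param ... Overrides passed to [patient_sim_config()].
#' @return A `patient_sim_config`.
#' @export
sim_nonresponder_config <- function(...) {
  args <- list(sv_max_ml = 75, operating_point = 2.5, ...)
  do.call(patient_sim_config, args[!duplicated(names(args), fromLast = TRUE)])
}

# beat schedule: times (s), labels, ventricular flags
sim_beat_schedule <- function(cfg) {
  rr0 <- 60 / cfg$hr_bpm
  t <- 0.5
  times <- t; labels <- "sinus"; vent <- FALSE
  sinus_run <- 1L
  while (TRUE) {
    rr <- rr0 + stats::rnorm(1, 0, cfg$rr_sd_ms / 1000) +
      (cfg$resp_rr_mod_ms / 1000) * sin(2 * pi * cfg$resp_rate_hz * t)
    rr <- max(rr, 0.32)
    if (t + 2.5 * rr > cfg$duration_s) break
    if (sinus_run >= 12L && stats::runif(1) < cfg$p_ectopic) {
      cpl <- stats::runif(1, cfg$coupling_range[1L], cfg$coupling_range[2L])
      is_vent <- stats::runif(1) < cfg$es_type_mix
      t_ect <- t + cpl * rr
      t_post <- if (is_vent) t + 2 * rr else t_ect + rr
      times <- c(times, t_ect, t_post)
      labels <- c(labels, "ectopic", "post_ectopic")
      vent <- c(vent, is_vent, FALSE)
      t <- t_post
      sinus_run <- 0L
    } else {
      t <- t + rr
      times <- c(times, t)
      labels <- c(labels, "sinus")
      vent <- c(vent, FALSE)
      sinus_run <- sinus_run + 1L
    }
  }
  data.frame(time_s = times, label = labels, ventricular = vent,
             stringsAsFactors = FALSE)
}

# ABP beat-shape weight as a function of time since the pulse foot (s):
# linear upstroke (so the intersecting-tangent foot coincides with the
# programmed onset) with a short parabolic cap at the peak, near-linear
# systolic decay with a dicrotic hump, then handled by the exponential
# windkessel tail outside this function
abp_wave_weight <- function(dt, t_up = 0.12, t_sys = 0.35, w_es = 0.25) {
  cap <- 0.015  # s, half-width of the rounded peak
  w0 <- (t_up - cap) / t_up
  w <- numeric(length(dt))
  r <- dt >= 0 & dt < (t_up - cap)
  w[r] <- dt[r] / t_up
  k <- dt >= (t_up - cap) & dt < (t_up + cap)
  u <- dt[k] - (t_up - cap)
  # slope-continuous parabola: slope 1/t_up at entry, apex at t_up,
  # symmetric exit; apex weight = 1 - cap/(2 t_up)
  w[k] <- w0 + u / t_up - u^2 / (2 * t_up * cap)
  s <- dt >= (t_up + cap) & dt < t_sys
  w[s] <- w0 - (w0 - w_es) * (dt[s] - t_up - cap) / (t_sys - t_up - cap) +
    0.06 * exp(-((dt[s] - 0.27) / 0.02)^2)
  w
}

# peak weight actually attained by the template (parabolic cap apex)
abp_wave_peak <- function(t_up = 0.12, cap = 0.015) 1 - cap / (2 * t_up)

#' Simulate a patient's ECG/ABP waveforms with ground truth
#'
#' Generates a beat schedule (sinus RR with jitter and respiratory
#' modulation, extrasystoles with compensatory pauses), derives per-beat
#' hemodynamics from the preload mechanism described in
#' [patient_sim_config()], renders the ABP as a smooth pulse template scaled
#' to each beat's (DBP, SBP) with an exponential diastolic tail, renders the
#' ECG as template PQRST complexes (widened QRS for ventricular ectopics),
#' adds Gaussian noise, and measures stroke volume before and after a
#' simulated fluid bolus.
#'
#' @param cfg A [patient_sim_config()].
#' @param patient_id Identifier for the emitted record.
#' @return A list with `record` (a [waveform_record()] at `cfg$fs`), `truth`
#'   (per-beat data frame: `time_s`, `label`, `ventricular`, `rr_prev_ms`,
#'   `preload`, `sv_ml`, `pep_ms`, `dbp_mmHg`, `sbp_mmHg`, `pp_mmHg`,
#'   `eligible`), `sv` (an [sv_series()]) and `config`.
#' @export
simulate_patient_waveforms <- function(cfg = patient_sim_config(),
                                       patient_id = "SIM001") {
  stopifnot(inherits(cfg, "patient_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rr0 <- 60 / cfg$hr_bpm
  sched <- sim_beat_schedule(cfg)
  nb <- nrow(sched)
  rr_prev <- c(NA_real_, diff(sched$time_s))          # s
  fill <- ifelse(is.na(rr_prev), 1, rr_prev / rr0)    # filling-time factor
  prev_ect <- c(FALSE, sched$label[-nb] == "ectopic")
  preload <- cfg$operating_point + cfg$preload_gain * (fill - 1) +
    cfg$resid_bonus * prev_ect
  sv <- starling_sv(preload, cfg$sv_max_ml, cfg$p50, cfg$slope_k)
  # the premature beat ejects poorly whatever the Starling regime:
  # scale its SV by the (truncated) filling fraction
  is_ect <- sched$label == "ectopic"
  sv[is_ect] <- sv[is_ect] * pmin(1, fill[is_ect])
  pp <- sv / cfg$compliance_ml_per_mmHg
  pep <- cfg$pep0_ms - cfg$pep_preload_coef_ms * (preload - cfg$operating_point) +
    stats::rnorm(nb, 0, cfg$pep_noise_sd_ms)
  pep <- pmax(pep, 60)
  foot <- sched$time_s + pep / 1000

  # diastolic chain: windkessel decay between consecutive pulse feet
  t_up <- 0.12; t_sys <- 0.35; w_es <- 0.25
  dbp <- numeric(nb)
  dbp[1L] <- 60
  for (i in seq_len(nb - 1L)) {
    p_es <- dbp[i] + pp[i] * w_es
    gap <- foot[i + 1L] - foot[i]
    dbp[i + 1L] <- if (gap <= t_sys) {
      dbp[i] + pp[i] * abp_wave_weight(gap, t_up, t_sys, w_es)
    } else {
      cfg$p_inf_mmHg + (p_es - cfg$p_inf_mmHg) *
        exp(-(gap - t_sys) / cfg$tau_windkessel_s)
    }
    dbp[i + 1L] <- max(dbp[i + 1L], cfg$p_inf_mmHg)
  }
  # rendered systolic peak sits at the parabolic cap apex
  sbp <- dbp + abp_wave_peak() * pp

  # render ABP
  tt <- seq(0, cfg$duration_s, by = 1 / cfg$fs)
  abp <- rep(dbp[1L], length(tt))
  idx_foot <- findInterval(tt, foot)   # 0 before first foot
  for (i in seq_len(nb)) {
    sel <- which(idx_foot == i)
    if (!length(sel)) next
    dt <- tt[sel] - foot[i]
    w <- abp_wave_weight(dt, t_up, t_sys, w_es)
    p <- dbp[i] + pp[i] * w
    tail_sel <- dt >= t_sys
    if (any(tail_sel)) {
      p_es <- dbp[i] + pp[i] * w_es
      p[tail_sel] <- cfg$p_inf_mmHg + (p_es - cfg$p_inf_mmHg) *
        exp(-(dt[tail_sel] - t_sys) / cfg$tau_windkessel_s)
    }
    abp[sel] <- p
  }

  # render ECG as template complexes
  ecg <- numeric(length(tt))
  gauss <- function(centre, amp, sd) {
    lo <- max(1L, ceiling((centre - 4 * sd) * cfg$fs) + 1L)
    hi <- min(length(tt), floor((centre + 4 * sd) * cfg$fs) + 1L)
    if (hi < lo) return(invisible(NULL))
    rng <- lo:hi
    ecg[rng] <<- ecg[rng] + amp * exp(-((tt[rng] - centre) / sd)^2 / 2)
    invisible(NULL)
  }
  for (i in seq_len(nb)) {
    tc <- sched$time_s[i]
    if (sched$ventricular[i]) {
      gauss(tc, 1.3, 0.022)
      gauss(tc + 0.08, -0.3, 0.02)
    } else {
      gauss(tc - 0.16, 0.10, 0.02)   # P
      gauss(tc - 0.028, -0.12, 0.008)  # Q
      gauss(tc, 1.0, 0.011)          # R
      gauss(tc + 0.028, -0.18, 0.009)  # S
      gauss(tc + 0.25, 0.22, 0.045)  # T
    }
  }
  if (cfg$ecg_noise_sd > 0)
    ecg <- ecg + stats::rnorm(length(tt), 0, cfg$ecg_noise_sd)
  if (cfg$abp_noise_sd_mmHg > 0)
    abp <- abp + stats::rnorm(length(tt), 0, cfg$abp_noise_sd_mmHg)

  # ground-truth eligibility under the analysis rules
  eligible <- rep(FALSE, nb)
  for (i in which(sched$label == "ectopic")) {
    if (i < 12L || i + 1L > nb) next
    base <- (i - 10L):(i - 1L)
    if (!all(sched$label[base] == "sinus")) next
    if (sched$label[i + 1L] != "post_ectopic") next
    ref <- stats::median(rr_prev[base])
    if (rr_prev[i] <= 0.8 * ref + 1e-12) eligible[i] <- TRUE
  }

  truth <- cbind(sched,
                 data.frame(rr_prev_ms = rr_prev * 1000, preload = preload,
                            sv_ml = sv, pep_ms = pep, dbp_mmHg = dbp,
                            sbp_mmHg = sbp, pp_mmHg = sbp - dbp,
                            foot_time_s = foot, eligible = eligible))

  sv_base_mean <- starling_sv(cfg$operating_point, cfg$sv_max_ml, cfg$p50,
                              cfg$slope_k)
  sv_post_mean <- starling_sv(cfg$operating_point + cfg$fluid_bolus_preload_shift,
                              cfg$sv_max_ml, cfg$p50, cfg$slope_k)
  svs <- sv_series(patient_id,
                   pmax(stats::rnorm(10, sv_base_mean, cfg$sv_noise_sd_ml), 1),
                   pmax(stats::rnorm(10, sv_post_mean, cfg$sv_noise_sd_ml), 1))

  rec <- waveform_record(ecg = ecg, abp = abp, fs = cfg$fs,
                         patient_id = patient_id)
  list(record = rec, truth = truth, sv = svs, config = cfg)
}
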