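test_that("cohort simulation is reproducible and internally consistent", {
  a <- simulate_cohort_summaries(cohort_sim_config(seed = 5))
  b <- simulate_cohort_summaries(cohort_sim_config(seed = 5))
  expect_identical(a, b)
  expect_equal(nrow(a), 26L)
  expect_equal(sum(a$responder_10), 6L)
  expect_equal(a$dsbp_rel, 100 * a$dsbp_abs / a$base_sbp)
  expect_equal(a$responder_10, a$dsv_rel_pct >= 10)
  expect_equal(a$sv_post_ml / a$sv_baseline_ml - 1, a$dsv_rel_pct / 100)
  expect_true(all(a$base_pp > 0))
  truth <- attr(a, "truth")
  expect_equal(truth$responder, a$responder_10)
})

test_that("cohort group draws match the configured distributions", {
  cfg <- cohort_sim_config(n_nonresp = 4000, n_resp = 1200, seed = 6)
  s <- simulate_cohort_summaries(cfg)
  nr <- !s$responder_10
  expect_equal(mean(s$dsbp_abs[nr]), -0.1, tolerance = 0.3)
  expect_equal(stats::sd(s$dsbp_abs[nr]), 5.6, tolerance = 0.2)
  expect_equal(mean(s$dpep_abs[!nr]), 7.5, tolerance = 0.3)
  expect_true(all(s$dsv_rel_pct[!nr] >= 10 & s$dsv_rel_pct[!nr] <= 30))
  expect_true(all(s$dsv_rel_pct[nr] >= -8 & s$dsv_rel_pct[nr] < 10))
})

test_that("cohort configuration rejects malformed parameters", {
  expect_error(cohort_sim_config(n_nonresp = -1), "non-negative")
  expect_error(cohort_sim_config(deltas_abs = list(sbp = c(0, -1, 1, 1))),
               "sbp")
  expect_error(cohort_sim_config(deltas_abs = list(sbp = c(0, 1, 1, 1))),
               "pep")   # remaining variables must still be present
})

test_that("the Starling surrogate is monotone with a plateau", {
  expect_equal(starling_sv(0, sv_max_ml = 100, p50 = 0, slope_k = 0.7), 50)
  p <- seq(-3, 6, by = 0.1)
  sv <- starling_sv(p)
  expect_true(all(diff(sv) > 0))
  expect_equal(starling_sv(10), 100, tolerance = 1e-3)
  # default configs put responders on the steep part, non-responders on the
  # plateau: the same bolus-sized preload shift crosses the 10 % threshold
  # only for the responder
  r <- patient_sim_config(seed = 1)
  shift_pct <- function(cfg) {
    s0 <- starling_sv(cfg$operating_point, cfg$sv_max_ml, cfg$p50, cfg$slope_k)
    s1 <- starling_sv(cfg$operating_point + cfg$fluid_bolus_preload_shift,
                      cfg$sv_max_ml, cfg$p50, cfg$slope_k)
    100 * (s1 - s0) / s0
  }
  expect_gt(shift_pct(r), 10)
  expect_lt(shift_pct(sim_nonresponder_config(seed = 1)), 10)
})

test_that("patient simulation is reproducible at a fixed seed", {
  a <- simulate_patient_waveforms(patient_sim_config(duration_s = 20, seed = 9))
  b <- simulate_patient_waveforms(patient_sim_config(duration_s = 20, seed = 9))
  expect_identical(a$record$abp, b$record$abp)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sv$baseline_values, b$sv$baseline_values)
})

test_that("simulated waveforms stay within physiological bounds", {
  sim <- simulate_patient_waveforms(
    patient_sim_config(duration_s = 60, p_ectopic = 0.05, seed = 10))
  expect_equal(sim$record$fs, 125)
  expect_true(all(sim$record$abp > 20 & sim$record$abp < 300))
  expect_lt(max(abs(sim$record$ecg)), 2)
  expect_true(all(sim$truth$rr_prev_ms[-1] > 300))
  expect_length(sim$sv$baseline_values, 10)
  expect_length(sim$sv$post_values, 10)
})

test_that("ventricular ectopics get a full compensatory pause", {
  cfg <- patient_sim_config(duration_s = 120, p_ectopic = 0.08,
                            rr_sd_ms = 0, resp_rr_mod_ms = 0,
                            es_type_mix = 1, seed = 13)
  tr <- simulate_patient_waveforms(cfg)$truth
  ect <- which(tr$label == "ectopic")
  expect_gt(length(ect), 0)
  rr0 <- 60000 / cfg$hr_bpm
  # coupling + pause = twice the (noise-free) sinus interval
  expect_equal(tr$rr_prev_ms[ect] + tr$rr_prev_ms[ect + 1],
               rep(2 * rr0, length(ect)), tolerance = 1e-9)
})

test_that("supraventricular ectopics reset the sinus node", {
  cfg <- patient_sim_config(duration_s = 120, p_ectopic = 0.08,
                            rr_sd_ms = 0, resp_rr_mod_ms = 0,
                            es_type_mix = 0, seed = 14)
  tr <- simulate_patient_waveforms(cfg)$truth
  ect <- which(tr$label == "ectopic")
  expect_gt(length(ect), 0)
  rr0 <- 60000 / cfg$hr_bpm
  expect_equal(tr$rr_prev_ms[ect + 1], rep(rr0, length(ect)),
               tolerance = 1e-9)
  expect_true(all(tr$rr_prev_ms[ect] < 0.81 * rr0))
})

test_that("the post-ectopic beat carries extra preload and stroke volume", {
  tr <- simulate_patient_waveforms(
    patient_sim_config(duration_s = 300, p_ectopic = 0.05, seed = 15))$truth
  post <- which(tr$label == "post_ectopic")
  sinus <- which(tr$label == "sinus")
  expect_gt(mean(tr$preload[post]), mean(tr$preload[sinus]))
  expect_gt(mean(tr$sv_ml[post]), mean(tr$sv_ml[sinus]))
  # the premature beat itself ejects less than sinus beats
  ect <- which(tr$label == "ectopic")
  expect_lt(mean(tr$sv_ml[ect]), mean(tr$sv_ml[sinus]))
  # ground-truth eligibility demands ten preceding sinus beats
  for (i in which(tr$eligible)) {
    expect_true(all(tr$label[(i - 10):(i - 1)] == "sinus"))
  }
})

test_that("a record without extrasystoles makes the method not applicable", {
  sim <- simulate_patient_waveforms(
    patient_sim_config(duration_s = 60, p_ectopic = 0, seed = 16))
  expect_false(any(sim$truth$label == "ectopic"))
  an <- analyze_record(sim$record, sim$sv)
  expect_null(an$summary)
  expect_match(paste(an$qc_log, collapse = "\n"), "not applicable")
})

test_that("patient configurations with impossible rhythms are rejected", {
  expect_error(patient_sim_config(coupling_range = c(0.5, 0.9)), "0.8")
  expect_error(patient_sim_config(hr_bpm = 200), "300 ms")
  expect_error(patient_sim_config(p_ectopic = 0.5), "0.2")
  expect_error(patient_sim_config(duration_s = 5), "positive")
})
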