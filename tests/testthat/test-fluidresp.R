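test_that("the classification fit evaluates every predictor at every threshold", {
  s <- simulate_cohort_summaries(cohort_sim_config(seed = 21))
  fit <- run_classification(s)
  expect_s3_class(fit, "fluidresp")
  expect_equal(nrow(fit$classification), 16L)   # 8 predictors x 2 thresholds
  expect_setequal(unique(fit$classification$sv_threshold_pct), c(10, 15))
  expect_equal(sort(fit$predictors),
               sort(c("dsbp_abs", "dsbp_rel", "dpep_abs", "dpep_rel",
                      "dpp_abs", "dpp_rel", "ddpdt_abs", "ddpdt_rel")))
  cm <- coef(fit)
  expect_equal(dim(cm), c(8L, 2L))
  expect_true(all(cm >= 0 & cm <= 1))
  # the AUC in the grid is exactly roc_auc on the same data
  a <- roc_auc(s$dsbp_abs, s$dsv_rel_pct >= 10)
  row <- subset(fit$classification,
                predictor == "dsbp_abs" & sv_threshold_pct == 10)
  expect_equal(row$auc, a$auc)
  expect_equal(row$ci_low, a$ci_low)
  expect_equal(row$n_resp, 6L)
  # group comparison at the primary threshold matches the pooled t
  g <- subset(fit$groups, predictor == "dsbp_abs")
  tt <- two_sample_t_pooled(s$dsbp_abs[s$dsv_rel_pct < 10],
                            s$dsbp_abs[s$dsv_rel_pct >= 10])
  expect_equal(g$p_two_sided, tt$p)
  expect_equal(g$mean_resp, mean(s$dsbp_abs[s$dsv_rel_pct >= 10]))
})

test_that("print, summary and plot methods run on a fitted model", {
  s <- simulate_cohort_summaries(cohort_sim_config(seed = 22))
  fit <- fluidresp(dsv_rel_pct ~ dsbp_abs + dpep_abs, s)
  expect_output(print(fit), "ROC areas")
  expect_output(summary(fit), "Classification characteristics")
  expect_output(summary(fit), "pooled t")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("predictions apply the fitted Youden cut-points", {
  s <- simulate_cohort_summaries(cohort_sim_config(seed = 23))
  fit <- fluidresp(dsv_rel_pct ~ dsbp_abs, s)
  thr <- fit$classification$youden_threshold[
    fit$classification$sv_threshold_pct == 10]
  pred <- predict(fit)
  expect_equal(pred$dsbp_abs, s$dsbp_abs > thr)
  new <- data.frame(dsbp_abs = c(thr - 1, thr + 1))
  expect_equal(predict(fit, new)$dsbp_abs, c(FALSE, TRUE))
  expect_equal(predict(fit, new, type = "score")$dsbp_abs, new$dsbp_abs)
})

test_that("simulate draws parametric cohorts from the fitted group structure", {
  s <- simulate_cohort_summaries(cohort_sim_config(seed = 24))
  fit <- fluidresp(dsv_rel_pct ~ dsbp_abs + dpp_abs, s)
  reps <- simulate(fit, nsim = 3, seed = 99)
  expect_length(reps, 3)
  expect_equal(nrow(reps[[1]]), 26L)
  expect_setequal(names(reps[[1]]), c("dsbp_abs", "dpp_abs", "dsv_rel_pct"))
  reps2 <- simulate(fit, nsim = 3, seed = 99)
  expect_identical(reps, reps2)
  # replicate cohorts can be refitted
  refit <- fluidresp(dsv_rel_pct ~ dsbp_abs + dpp_abs, reps[[1]])
  expect_s3_class(refit, "fluidresp")
})

test_that("rows with a missing predictor are dropped for that predictor only", {
  s <- simulate_cohort_summaries(cohort_sim_config(seed = 25))
  s$dpep_abs[1:3] <- NA
  fit <- run_classification(s)
  cl <- fit$classification
  n_pep <- with(subset(cl, predictor == "dpep_abs" & sv_threshold_pct == 10),
                n_resp + n_nonresp)
  n_sbp <- with(subset(cl, predictor == "dsbp_abs" & sv_threshold_pct == 10),
                n_resp + n_nonresp)
  expect_equal(n_pep, 23L)
  expect_equal(n_sbp, 26L)
})

test_that("a single-class cohort yields no AUC with an explicit reason", {
  s <- simulate_cohort_summaries(cohort_sim_config(n_resp = 0, seed = 26))
  fit <- run_classification(s)
  expect_true(all(is.na(fit$classification$auc)))
  expect_true(all(fit$classification$reason == "single class present"))
})

test_that("the formula interface requires a response and a predictor", {
  s <- simulate_cohort_summaries(cohort_sim_config(seed = 27))
  expect_error(fluidresp(~dsbp_abs, s), "response")
  expect_error(fluidresp(dsv_rel_pct ~ 1, s), "predictor")
  expect_error(run_classification(s[, c("patient_id", "dsv_rel_pct")]),
               "no standard")
})

test_that("simulated summaries and pipeline summaries are interchangeable", {
  s <- simulate_cohort_summaries(cohort_sim_config(seed = 28))
  p <- tempfile(fileext = ".csv")
  write_patient_summaries(s, p)
  fit_disk <- run_classification(read_patient_summaries(p))
  fit_mem <- run_classification(s)
  expect_equal(coef(fit_disk), coef(fit_mem), tolerance = 1e-10)
})

test_that("the cohort pipeline analyzes waveforms end to end", {
  sims <- c(
    lapply(1:2, function(k) simulate_patient_waveforms(
      patient_sim_config(duration_s = 180, p_ectopic = 0.08, seed = 30 + k),
      patient_id = sprintf("R%02d", k))),
    lapply(1:2, function(k) simulate_patient_waveforms(
      sim_nonresponder_config(duration_s = 180, p_ectopic = 0.08,
                              seed = 40 + k),
      patient_id = sprintf("N%02d", k))))
  res <- analyze_cohort(sims)
  expect_s3_class(res, "cohort_analysis")
  expect_equal(nrow(res$summaries), 4L)
  expect_s3_class(res$fit, "fluidresp")
  expect_equal(sum(res$summaries$responder_10), 2L)
  expect_output(print(res), "4 patient")
  # per-patient analyses carry beats, features, deltas and a QC log
  an <- res$analyses[["R01"]]
  expect_s3_class(an$beats, "beat_annotations")
  expect_s3_class(an$features, "beat_features")
  expect_gt(nrow(an$deltas), 0)
  expect_true(is.character(res$qc_log))
})

test_that("patients missing from the SV table are reported and kept out of the fit", {
  sims <- lapply(1:3, function(k) simulate_patient_waveforms(
    patient_sim_config(duration_s = 120, p_ectopic = 0.08, seed = 50 + k),
    patient_id = sprintf("P%02d", k)))
  recs <- lapply(sims, `[[`, "record")
  svl <- list(P01 = sims[[1]]$sv, P02 = sims[[2]]$sv)
  res <- analyze_cohort(recs, sv_list = svl, classify = FALSE)
  expect_match(paste(res$qc_log, collapse = "\n"), "P03.*missing from SV")
  expect_true(is.na(res$summaries$responder_10[
    res$summaries$patient_id == "P03"]))
})
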