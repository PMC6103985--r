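#' Fit the fluid-responsiveness classification model
#'
#' Evaluates per-patient post-ectopic changes as predictors of a
#' stroke-volume (SV) response to volume expansion. The left-hand side of
#' `formula` names the relative SV change (%) column; each right-hand-side
#' term is a candidate predictor (e.g. the aggregated absolute or relative
#' post-ectopic SBP change). For every predictor and every SV response
#' threshold the model computes the ROC area with its DeLong confidence
#' interval, the Youden-optimal threshold with sensitivity, specificity,
#' positive and negative predictive values, and a responder versus
#' non-responder group comparison (pooled Student's t) at the primary
#' threshold.
#'
#' @param formula e.g. `dsv_rel_pct ~ dsbp_abs + dsbp_rel + dpep_abs`.
#' @param data A `patient_summary` data frame (one row per patient); rows
#'   with a missing predictor are dropped for that predictor only,
#'   mirroring per-variable QC exclusion.
#' @param sv_thresholds SV response thresholds in percent; the first is the
#'   primary definition of fluid responsiveness.
#' @param conf_level Confidence level for DeLong intervals.
#' @param strict If `TRUE`, responders satisfy `dsv > threshold`; default
#'   non-strict (`>=`).
#' @return An object of class `fluidresp` with components `classification`
#'   (one row per predictor x threshold: AUC, CI, Youden threshold,
#'   sens/spec/PPV/NPV, group sizes), `groups` (per-predictor responder vs
#'   non-responder means, SDs and pooled-t p at the primary threshold),
#'   `scores` (the predictor matrix), `dsv`, `call` and `sv_thresholds`.
#'   Methods: [print.fluidresp()], [summary.fluidresp()],
#'   [coef.fluidresp()], [predict.fluidresp()], [plot.fluidresp()],
#'   [simulate.fluidresp()].
#' @seealso [run_classification()] for the all-standard-predictors wrapper.
#' @export
fluidresp <- function(formula, data, sv_thresholds = c(10, 15),
                      conf_level = 0.95, strict = FALSE) {
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  dsv <- stats::model.response(mf)
  if (is.null(dsv)) stop("formula needs a response: the relative SV change")
  preds <- attr(stats::terms(formula, data = data), "term.labels")
  if (!length(preds)) stop("formula needs at least one predictor")
  cmp <- if (strict) `>` else `>=`

  cls <- list(); grp <- list()
  for (thr in sv_thresholds) {
    labels <- cmp(dsv, thr)
    for (v in preds) {
      scores <- mf[[v]]
      ok <- !is.na(scores) & !is.na(labels)
      row <- data.frame(predictor = v, sv_threshold_pct = thr,
                        n_resp = sum(labels[ok]), n_nonresp = sum(!labels[ok]),
                        auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        youden_threshold = NA_real_, sens_pct = NA_real_,
                        spec_pct = NA_real_, ppv_pct = NA_real_,
                        npv_pct = NA_real_, reason = "",
                        stringsAsFactors = FALSE)
      if (row$n_resp < 1L || row$n_nonresp < 1L) {
        row$reason <- "single class present"
      } else {
        a <- roc_auc(scores[ok], labels[ok], conf_level = conf_level)
        yt <- withCallingHandlers(
          youden_threshold(scores[ok], labels[ok]),
          warning = function(w) invokeRestart("muffleWarning"))
        cs <- confusion_stats(yt$tp, yt$fn, yt$fp, yt$tn)
        row$auc <- a$auc; row$ci_low <- a$ci_low; row$ci_high <- a$ci_high
        row$youden_threshold <- yt$threshold
        row$sens_pct <- cs$sens_pct; row$spec_pct <- cs$spec_pct
        row$ppv_pct <- cs$ppv_pct; row$npv_pct <- cs$npv_pct
      }
      cls[[length(cls) + 1L]] <- row
    }
  }
  # group comparison at the primary SV threshold
  labels1 <- cmp(dsv, sv_thresholds[1L])
  for (v in preds) {
    scores <- mf[[v]]
    ok <- !is.na(scores) & !is.na(labels1)
    xr <- scores[ok & labels1]; xn <- scores[ok & !labels1]
    row <- data.frame(predictor = v,
                      mean_nonresp = if (length(xn)) mean(xn) else NA_real_,
                      sd_nonresp = if (length(xn) > 1) stats::sd(xn) else NA_real_,
                      n_nonresp = length(xn),
                      mean_resp = if (length(xr)) mean(xr) else NA_real_,
                      sd_resp = if (length(xr) > 1) stats::sd(xr) else NA_real_,
                      n_resp = length(xr),
                      t_stat = NA_real_, p_two_sided = NA_real_,
                      stringsAsFactors = FALSE)
    if (length(xr) >= 2L && length(xn) >= 2L &&
        stats::sd(xr) > 0 && stats::sd(xn) > 0) {
      tt <- two_sample_t_pooled(xn, xr)
      row$t_stat <- tt$t; row$p_two_sided <- tt$p
    }
    grp[[length(grp) + 1L]] <- row
  }

  structure(list(call = match.call(),
                 formula = formula,
                 sv_thresholds = sv_thresholds,
                 conf_level = conf_level,
                 strict = strict,
                 predictors = preds,
                 scores = mf[preds],
                 dsv = dsv,
                 classification = do.call(rbind, cls),
                 groups = do.call(rbind, grp)),
            class = "fluidresp")
}

#' Classification grid over all standard post-ectopic predictors
#'
#' Fits [fluidresp()] with the standard eight predictors (absolute and
#' relative post-ectopic changes of SBP, PEP, PP and dP/dt max) against the
#' relative SV change, at the 10 % and 15 % SV response thresholds.
#'
#' @param summaries A `patient_summary` data frame (pipeline output or
#'   [simulate_cohort_summaries()] output).
#' @param ... Passed to [fluidresp()].
#' @return A `fluidresp` object.
#' @export
run_classification <- function(summaries, ...) {
  summaries <- as.data.frame(summaries)
  std <- as.vector(t(outer(paste0("d", names(.delta_vars)), c("_abs", "_rel"),
                           paste0)))
  have <- std[std %in% names(summaries)]
  if (!length(have)) stop("no standard post-ectopic delta columns found")
  f <- stats::reformulate(have, response = "dsv_rel_pct")
  fit <- fluidresp(f, summaries, ...)
  fit$call <- match.call()
  fit
}

#' @export
print.fluidresp <- function(x, ...) {
  cat("Fluid-responsiveness classification from post-ectopic beat changes\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Patients: %d  (responders at %g%% SV threshold: %d)\n",
              length(x$dsv), x$sv_thresholds[1L],
              sum((if (x$strict) `>` else `>=`)(x$dsv, x$sv_thresholds[1L]),
                  na.rm = TRUE)))
  cat("ROC areas (primary threshold):\n")
  print(round(coef(x)[, 1, drop = FALSE], 2))
  invisible(x)
}

#' Summarise a fluidresp fit
#'
#' @param object A `fluidresp` object.
#' @param digits Digits for printed percentages and AUCs.
#' @param ... Unused.
#' @return `object`, invisibly, after printing the classification grid
#'   (AUC \[CI\], Youden threshold, sensitivity/specificity/PPV/NPV per
#'   predictor and SV threshold) and the responder vs non-responder group
#'   comparison.
#' @export
summary.fluidresp <- function(object, digits = 2, ...) {
  cat("Classification characteristics of post-ectopic changes\n\n")
  cl <- object$classification
  show <- data.frame(predictor = cl$predictor,
                     sv_thr = cl$sv_threshold_pct,
                     auc = sprintf("%.*f [%.*f; %.*f]", digits, cl$auc,
                                   digits, cl$ci_low, digits, cl$ci_high),
                     threshold = signif(cl$youden_threshold, 3),
                     sens = round(cl$sens_pct), spec = round(cl$spec_pct),
                     ppv = round(cl$ppv_pct), npv = round(cl$npv_pct),
                     stringsAsFactors = FALSE)
  print(show, row.names = FALSE)
  cat("\nResponders vs non-responders (primary SV threshold, pooled t):\n\n")
  g <- object$groups
  gs <- data.frame(predictor = g$predictor,
                   nonresp = sprintf("%.1f (%.1f) n=%d", g$mean_nonresp,
                                     g$sd_nonresp, g$n_nonresp),
                   resp = sprintf("%.1f (%.1f) n=%d", g$mean_resp,
                                  g$sd_resp, g$n_resp),
                   p = sprintf("%.2f", g$p_two_sided),
                   stringsAsFactors = FALSE)
  print(gs, row.names = FALSE)
  invisible(object)
}

#' ROC areas of a fluidresp fit
#'
#' @param object A `fluidresp` object.
#' @param ... Unused.
#' @return A numeric matrix of AUCs: predictors in rows, one column per SV
#'   response threshold.
#' @export
coef.fluidresp <- function(object, ...) {
  cl <- object$classification
  thr <- unique(cl$sv_threshold_pct)
  m <- sapply(thr, function(t) cl$auc[cl$sv_threshold_pct == t])
  m <- matrix(m, nrow = length(object$predictors),
              dimnames = list(object$predictors, paste0("auc_", thr)))
  m
}

#' Predict fluid responsiveness for new patients
#'
#' Applies the fitted Youden-optimal thresholds: a patient is predicted a
#' responder when the predictor exceeds (strictly) the threshold.
#'
#' @param object A `fluidresp` object.
#' @param newdata Data frame with the predictor columns; defaults to the
#'   training data.
#' @param sv_threshold Which fitted SV threshold's cut-points to use.
#' @param type `"class"` for logical predictions, `"score"` to return the
#'   predictor values.
#' @param ... Unused.
#' @return A data frame (patients x predictors) of logicals or scores.
#' @export
predict.fluidresp <- function(object, newdata = NULL,
                              sv_threshold = object$sv_thresholds[1L],
                              type = c("class", "score"), ...) {
  type <- match.arg(type)
  sc <- if (is.null(newdata)) object$scores
        else as.data.frame(newdata)[, object$predictors, drop = FALSE]
  if (type == "score") return(sc)
  cl <- object$classification
  cl <- cl[cl$sv_threshold_pct == sv_threshold, ]
  if (!nrow(cl)) stop("no fitted cut-points at SV threshold ", sv_threshold)
  out <- sc
  for (v in object$predictors)
    out[[v]] <- sc[[v]] > cl$youden_threshold[cl$predictor == v]
  out
}

#' ROC curves of a fluidresp fit
#'
#' Plots empirical ROC curves (base graphics) for the chosen predictors at
#' one SV response threshold.
#'
#' @param x A `fluidresp` object.
#' @param predictors Predictor names to draw; defaults to all.
#' @param sv_threshold SV response threshold to use.
#' @param col Line colours, recycled.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fluidresp <- function(x, predictors = x$predictors,
                           sv_threshold = x$sv_thresholds[1L],
                           col = seq_along(predictors), ...) {
  cmp <- if (x$strict) `>` else `>=`
  labels <- cmp(x$dsv, sv_threshold)
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  col <- rep_len(col, length(predictors))
  auc_leg <- character(length(predictors))
  for (k in seq_along(predictors)) {
    v <- predictors[k]
    sc <- x$scores[[v]]
    ok <- !is.na(sc) & !is.na(labels)
    crd <- roc_curve_points(sc[ok], labels[ok])
    graphics::lines(1 - crd$spec, crd$sens, col = col[k], lwd = 2)
    auc_leg[k] <- sprintf("%s (AUC %.2f)", v, roc_auc(sc[ok], labels[ok])$auc)
  }
  graphics::legend("bottomright", legend = auc_leg, col = col, lwd = 2,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Empirical ROC curve coordinates
#'
#' @inheritParams roc_auc
#' @return A data frame of `threshold`, `sens`, `spec` over all cut-points
#'   (including the -Inf/+Inf extremes), under the rule
#'   "positive iff score > threshold".
#' @export
roc_curve_points <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- c(-Inf, sort(unique(scores)), Inf)
  x <- scores[labels]; y <- scores[!labels]
  data.frame(threshold = u,
             sens = vapply(u, function(t) mean(x > t), numeric(1)),
             spec = vapply(u, function(t) mean(y <= t), numeric(1)))
}

#' Simulate cohorts from a fitted group structure
#'
#' Draws replicate patient-summary cohorts from the fitted responder and
#' non-responder group means and SDs (normal within each group, observed
#' group sizes), for parametric-bootstrap style exploration of the
#' classification statistics.
#'
#' @param object A `fluidresp` object.
#' @param nsim Number of replicate cohorts.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames, each with the predictor columns and
#'   a `dsv_rel_pct` column placing patients on the fitted responder side.
#' @export
simulate.fluidresp <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  g <- object$groups
  thr <- object$sv_thresholds[1L]
  n0 <- g$n_nonresp[1L]; n1 <- g$n_resp[1L]
  lapply(seq_len(nsim), function(i) {
    cols <- lapply(seq_len(nrow(g)), function(k) {
      c(stats::rnorm(n0, g$mean_nonresp[k], g$sd_nonresp[k]),
        stats::rnorm(n1, g$mean_resp[k], g$sd_resp[k]))
    })
    names(cols) <- g$predictor
    df <- as.data.frame(cols)
    df$dsv_rel_pct <- c(rep(thr - 5, n0), rep(thr + 5, n1))
    df
  })
}
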