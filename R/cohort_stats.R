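#' ROC area under the curve with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney two-sample statistic: the probability that a
#' randomly chosen responder scores higher than a randomly chosen
#' non-responder, ties counted one half. The confidence interval uses the
#' DeLong placement-variance estimator with normal quantiles, clipped to
#' \[0, 1\]. Orientation is fixed a priori: larger scores indicate
#' responders (no automatic direction flip).
#'
#' @param scores Numeric predictor values.
#' @param labels Logical (or 0/1) responder indicator, same length.
#' @param conf_level Confidence level for the DeLong interval.
#' @return A list with `auc`, `ci_low`, `ci_high`, `se`, `n_resp`,
#'   `n_nonresp` and `conf_level`.
#' @export
#' @examples
#' roc_auc(c(1, 2, 3, 2.5, 4), c(FALSE, FALSE, FALSE, TRUE, TRUE))$auc  # 5/6
roc_auc <- function(scores, labels, conf_level = 0.95) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  x <- scores[labels]    # responders
  y <- scores[!labels]   # non-responders
  m <- length(x); n <- length(y)
  if (m < 1L || n < 1L)
    stop("both classes must be present to compute a ROC area")
  r <- rank(c(x, y), ties.method = "average")
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  # DeLong placements
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  s10 <- if (m > 1L) stats::var(v10) else 0
  s01 <- if (n > 1L) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = auc,
       ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se),
       se = se, n_resp = m, n_nonresp = n, conf_level = conf_level)
}

#' Optimal classification threshold by the Youden index
#'
#' Evaluates every candidate cut-point (midpoints of adjacent sorted unique
#' scores, plus the two extreme cut-points `-Inf` / `Inf` that classify
#' everyone positive or negative) under the decision rule "positive iff
#' score > threshold" and returns the one maximising
#' J = sensitivity + specificity - 1. Ties in J are broken toward higher
#' specificity, then toward the lower threshold.
#'
#' @inheritParams roc_auc
#' @return A list with `threshold` (native score units), `sens_pct`,
#'   `spec_pct`, `j` and the confusion counts `tp`, `fn`, `fp`, `tn` at the
#'   threshold. With all scores identical the threshold is degenerate
#'   (J = 0) and a warning is issued.
#' @export
youden_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  x <- scores[labels]; y <- scores[!labels]
  if (!length(x) || !length(y))
    stop("both classes must be present to compute a threshold")
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    warning("all scores identical: degenerate threshold (J = 0)")
    cand <- c(-Inf, Inf)
  } else {
    cand <- c(-Inf, (u[-1L] + u[-length(u)]) / 2, Inf)
  }
  sens <- vapply(cand, function(t) mean(x > t), numeric(1))
  spec <- vapply(cand, function(t) mean(y <= t), numeric(1))
  j <- sens + spec - 1
  best <- order(-j, -spec, cand)[1L]
  t0 <- cand[best]
  list(threshold = t0,
       sens_pct = 100 * sens[best], spec_pct = 100 * spec[best],
       j = j[best],
       tp = sum(x > t0), fn = sum(x <= t0),
       fp = sum(y > t0), tn = sum(y <= t0))
}

#' Confusion-matrix classification statistics
#'
#' @param tp,fn,fp,tn Non-negative integer counts (true/false
#'   positives/negatives).
#' @return A list with `sens_pct`, `spec_pct`, `ppv_pct`, `npv_pct` (exact
#'   percentages; `NA` for zero denominators) and a `rounded` sub-list with
#'   the same quantities rounded to the nearest integer for reporting.
#' @export
#' @examples
#' confusion_stats(tp = 4, fn = 2, fp = 0, tn = 20)$rounded  # 67/100/100/91
confusion_stats <- function(tp, fn, fp, tn) {
  cnt <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers")
  ratio <- function(a, b) if (b > 0) 100 * a / b else NA_real_
  out <- list(sens_pct = ratio(tp, tp + fn),
              spec_pct = ratio(tn, tn + fp),
              ppv_pct = ratio(tp, tp + fp),
              npv_pct = ratio(tn, tn + fn))
  out$rounded <- lapply(out, function(v) if (is.na(v)) NA_real_ else round(v))
  out
}

#' Pooled-variance two-sample Student's t test
#'
#' Accepts either raw vectors (`two_sample_t_pooled(x, y)`) or summary
#' statistics (`two_sample_t_pooled(m1, s1, n1, m2, s2, n2)`), so group
#' comparisons published only as mean (SD) per group can be checked
#' directly. Both paths give identical results on the same data.
#'
#' @param m1 First group: raw numeric vector, or its mean.
#' @param s1 First group SD (summary path), or the second group's raw vector
#'   when `m1` is a vector.
#' @param n1,m2,s2,n2 Remaining summary statistics (summary path only).
#' @return A list with `t`, `df`, `p` (two-sided), `mean_diff` and the group
#'   summaries.
#' @export
#' @examples
#' two_sample_t_pooled(-0.1, 5.6, 20, 5.9, 6.6, 6)$p  # ~0.037
two_sample_t_pooled <- function(m1, s1 = NULL, n1 = NULL,
                                m2 = NULL, s2 = NULL, n2 = NULL) {
  if (is.null(n1) && length(m1) > 1L && length(s1) > 1L) {
    x <- m1; y <- s1
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    m2 <- mean(y); s2 <- stats::sd(y); n2 <- length(y)
    n1 <- length(x); s1 <- stats::sd(x); m1 <- mean(x)
  }
  if (any(c(n1, n2) < 2L)) stop("each group needs n >= 2")
  if (any(c(s1, s2) <= 0)) stop("group SDs must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m2 - m1) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_diff = m2 - m1,
       mean1 = m1, sd1 = s1, n1 = n1, mean2 = m2, sd2 = s2, n2 = n2)
}

#' Paired Student's t test
#'
#' Standard paired t test on before/after vectors, with explicit handling of
#' degenerate zero-variance differences: identical pairs give t = 0, p = 1;
#' a constant non-zero shift is reported as p = 0 with a warning.
#'
#' @param before,after Paired numeric vectors of equal length >= 2.
#' @return A list with `t`, `df`, `p` and `mean_diff` (after - before).
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) stop("paired vectors differ in length")
  ok <- !is.na(before) & !is.na(after)
  d <- after[ok] - before[ok]
  if (length(d) < 2L) stop("need at least 2 complete pairs")
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0))
    warning("zero-variance non-zero differences: p reported as 0")
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                mean_diff = mean(d)))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; p-value by the
#' t-approximation. A constant vector yields an undefined (missing) rho.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `rho` and `p` (both `NA` when undefined).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
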