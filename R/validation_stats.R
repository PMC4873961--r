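# Discrimination, calibration and meta-analysis machinery for validating a
# probabilistic CS scoring model:
#   - ROC curve and AUC via the rank (Mann-Whitney) statistic, ties counted
#     one half; standard error by the Hanley-McNeil formula;
#   - ROC-derived cut-off maximising Youden's J;
#   - classification table with sensitivity, specificity, diagnostic odds
#     ratio and percent correctly classified;
#   - calibration by quintiles of predicted probability;
#   - DerSimonian-Laird random-effects meta-analysis of study AUCs.

.check_binary <- function(outcomes) {
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be 0/1")
}

#' ROC curve and area under it
#'
#' AUC is computed as the Mann-Whitney concordance probability
#' P(score_case > score_control) + 1/2 P(tie), via average ranks; its
#' standard error uses the Hanley-McNeil formula. Curve points are evaluated
#' at every distinct score threshold (prediction rule: score >= threshold),
#' starting at (0,0) and ending at (1,1).
#'
#' @param probs Numeric scores (typically predicted probabilities).
#' @param outcomes 0/1 vector, 1 = caesarean section (case).
#' @return A `roc_result`: list with `auc`, `se`, `points` (data.frame
#'   `threshold`, `fpr`, `tpr`; first row threshold = Inf), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(probs, outcomes) {
  stopifnot(length(probs) == length(outcomes), !anyNA(probs), !anyNA(outcomes))
  .check_binary(outcomes)
  n_pos <- sum(outcomes == 1)
  n_neg <- sum(outcomes == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate input: need at least one case and one control")
  }
  rk <- rank(probs)                        # average ranks handle ties as 1/2
  auc <- (sum(rk[outcomes == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
              (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  thr <- sort(unique(probs), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(probs >= t & outcomes == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(probs >= t & outcomes == 0) / n_neg,
                numeric(1))
  points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                       tpr = c(0, tpr))
  if (points$fpr[nrow(points)] < 1 || points$tpr[nrow(points)] < 1) {
    points <- rbind(points, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  structure(list(auc = auc, se = se, points = points,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (SE %.4f), %d cases / %d controls, %d thresholds\n",
              x$auc, x$se, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' ROC-derived probability cut-off
#'
#' Chooses the finite threshold maximising Youden's J = sensitivity +
#' specificity - 1; ties are broken toward the higher-specificity (higher)
#' threshold. The returned cut-off is the midpoint between the chosen
#' threshold and the next lower distinct score, which classifies identically
#' but sits in the middle of the separating gap.
#'
#' @param roc A `roc_result`.
#' @return Probability cut-off (scalar).
#' @export
roc_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  p <- roc$points
  finite <- is.finite(p$threshold)
  j <- p$tpr - p$fpr
  j[!finite] <- -Inf
  # thresholds are in decreasing order; which.max takes the first (highest
  # threshold = highest specificity) among ties
  best <- which.max(j)
  t_star <- p$threshold[best]
  lower <- p$threshold[is.finite(p$threshold) & p$threshold < t_star]
  if (length(lower) > 0) (t_star + max(lower)) / 2 else t_star
}

#' Classification table at a probability cut-off
#'
#' Predicts caesarean section iff probability >= cutoff (the >= rule matters
#' at tied scores and is deliberate). The diagnostic odds ratio is
#' (tp x tn)/(fp x fn); with an empty cell it is reported as Inf (or 0) with
#' a warning unless `continuity = TRUE`, which adds 0.5 to every cell for the
#' DOR only.
#'
#' @param probs Numeric scores.
#' @param outcomes 0/1 vector.
#' @param cutoff Probability cut-off in (0, 1).
#' @param continuity Apply the 0.5 continuity correction to the DOR when a
#'   cell is zero (default FALSE).
#' @return A `classification_table`: list with `cutoff`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `dor`, `pct_correct`.
#' @export
classification_table <- function(probs, outcomes, cutoff,
                                 continuity = FALSE) {
  stopifnot(length(probs) == length(outcomes), cutoff > 0, cutoff < 1)
  .check_binary(outcomes)
  pred <- probs >= cutoff
  tp <- sum(pred & outcomes == 1)
  fp <- sum(pred & outcomes == 0)
  fn <- sum(!pred & outcomes == 1)
  tn <- sum(!pred & outcomes == 0)
  if (min(tp, fp, tn, fn) == 0) {
    if (continuity) {
      dor <- ((tp + 0.5) * (tn + 0.5)) / ((fp + 0.5) * (fn + 0.5))
    } else {
      warning("zero cell in classification table; diagnostic odds ratio degenerate",
              call. = FALSE)
      dor <- (tp * tn) / (fp * fn)          # Inf, 0 or NaN as appropriate
    }
  } else {
    dor <- (tp * tn) / (fp * fn)
  }
  structure(list(
    cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    dor = dor, pct_correct = 100 * (tp + tn) / (tp + fp + tn + fn)),
    class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  cat(sprintf("<classification_table> cutoff %.4f\n", x$cutoff))
  cat(sprintf("  tp %d  fp %d  tn %d  fn %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  DOR %.2f  %% correct %.1f\n",
              x$sensitivity, x$specificity, x$dor, x$pct_correct))
  invisible(x)
}

#' Calibration by quintiles of predicted probability
#'
#' Records are ranked by predicted probability and split into five
#' near-equal bins (when n is not a multiple of 5 the remainder goes to the
#' lowest bins). Within each bin the mean predicted probability is compared
#' with the observed event proportion; for a calibrated model the two track
#' each other.
#'
#' @param probs Numeric predicted probabilities.
#' @param outcomes 0/1 vector.
#' @return Data.frame with columns `bin` (1 = lowest probabilities), `n`,
#'   `mean_predicted`, `observed_rate`.
#' @export
calibration_quintiles <- function(probs, outcomes) {
  stopifnot(length(probs) == length(outcomes))
  .check_binary(outcomes)
  n <- length(probs)
  if (n < 5) stop("need at least 5 records for quintile calibration")
  ord <- order(probs)
  base <- n %/% 5L
  extra <- n %% 5L
  sizes <- rep(base, 5L) + c(rep(1L, extra), rep(0L, 5L - extra))
  bin <- rep(1:5, times = sizes)
  p <- probs[ord]; y <- outcomes[ord]
  data.frame(
    bin = 1:5,
    n = sizes,
    mean_predicted = as.numeric(tapply(p, bin, mean)),
    observed_rate = as.numeric(tapply(y, bin, mean))
  )
}

#' DerSimonian-Laird random-effects meta-analysis of AUCs
#'
#' Pools per-study AUC estimates with a random-effects model: fixed-effect
#' weights 1/se^2 give Cochran's Q; the between-study variance is
#' tau^2 = max(0, (Q - df)/C) with C = sum(w) - sum(w^2)/sum(w); the pooled
#' estimate uses weights 1/(se^2 + tau^2) with a 95% normal confidence
#' interval; heterogeneity is summarised by I^2 = max(0, (Q - df)/Q).
#'
#' @param auc Per-study AUC estimates, or a data.frame with columns `auc`
#'   and `se` (optionally `study_id`).
#' @param se Per-study standard errors (> 0); ignored when `auc` is a
#'   data.frame.
#' @return A `meta_analysis`: list with `pooled`, `ci_low`, `ci_high`,
#'   `tau2`, `i2`, `q`, `k`, and `studies` (data.frame with random-effects
#'   `weight`, normalised to sum to 1).
#' @export
meta_auc <- function(auc, se = NULL) {
  if (is.data.frame(auc)) {
    df <- auc
    stopifnot(all(c("auc", "se") %in% names(df)))
    se <- df$se
    sid <- if ("study_id" %in% names(df)) as.character(df$study_id) else
      as.character(seq_len(nrow(df)))
    auc <- df$auc
  } else {
    sid <- as.character(seq_along(auc))
  }
  k <- length(auc)
  if (k == 0) stop("no studies supplied")
  stopifnot(length(se) == k, all(se > 0))
  w <- 1 / se^2
  fixed <- sum(w * auc) / sum(w)
  q <- sum(w * (auc - fixed)^2)
  df_q <- k - 1
  if (df_q > 0) {
    c_const <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - df_q) / c_const)
    i2 <- max(0, (q - df_q) / q)
  } else {
    tau2 <- 0
    i2 <- 0
  }
  w_re <- 1 / (se^2 + tau2)
  pooled <- sum(w_re * auc) / sum(w_re)
  se_pooled <- sqrt(1 / sum(w_re))
  structure(list(
    pooled = pooled,
    ci_low = pooled - stats::qnorm(0.975) * se_pooled,
    ci_high = pooled + stats::qnorm(0.975) * se_pooled,
    se = se_pooled, tau2 = tau2, i2 = i2, q = q, k = k,
    studies = data.frame(study_id = sid, auc = auc, se = se,
                         weight = w_re / sum(w_re))),
    class = "meta_analysis")
}

#' @export
print.meta_analysis <- function(x, ...) {
  cat(sprintf("<meta_analysis> %d studies: pooled AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$k, x$pooled, x$ci_low, x$ci_high))
  cat(sprintf("  tau^2 %.5f  I^2 %.1f%%  Q %.2f\n", x$tau2, 100 * x$i2, x$q))
  invisible(x)
}

#' Full discrimination/calibration validation of a dataset
#'
#' Convenience wrapper: predicts under the chosen version, then computes the
#' ROC/AUC, the Youden cut-off, the classification table at that cut-off and
#' the quintile calibration, over the records that are both predictable and
#' have a recorded mode of delivery.
#'
#' @inheritParams cs_benchmark
#' @return List with `version`, `n_used`, `roc`, `cutoff`, `classification`,
#'   `calibration`.
#' @export
validate_model <- function(ds, version = "auto", age_cutoff = 35) {
  preds <- predict_dataset(ds, version = version, age_cutoff = age_cutoff)
  r <- ds$records
  use <- !is.na(preds$probability) & !is.na(r$mode_of_delivery)
  if (!any(use)) stop("no usable records")
  p <- preds$probability[use]
  y <- as.numeric(r$mode_of_delivery[use] == "caesarean")
  roc <- roc_auc(p, y)
  cut <- roc_cutoff(roc)
  list(version = attr(preds, "version"), n_used = sum(use), roc = roc,
       cutoff = cut,
       classification = classification_table(p, y, cut),
       calibration = calibration_quintiles(p, y))
}
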