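# ROC/AUC, cut-off, classification table, calibration, meta-analysis.

test_that("AUC matches trivial cases and the O(n^2) concordance oracle", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$n_pos, 2); expect_equal(r$n_neg, 2)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(1207)
  for (i in 1:5) {
    probs <- round(runif(200), 2)      # rounding forces ties
    y <- rbinom(200, 1, plogis(4 * probs - 2))
    if (length(unique(y)) < 2) next
    r <- roc_auc(probs, y)
    expect_equal(r$auc, oracle_auc(probs, y), tolerance = 1e-12)
  }
})

test_that("ROC curve points run monotonically from (0,0) to (1,1)", {
  set.seed(8)
  probs <- runif(100); y <- rbinom(100, 1, probs)
  p <- roc_auc(probs, y)$points
  expect_equal(p$fpr[1], 0); expect_equal(p$tpr[1], 0)
  expect_equal(p$fpr[nrow(p)], 1); expect_equal(p$tpr[nrow(p)], 1)
  expect_true(all(diff(p$fpr) >= 0))
  expect_true(all(diff(p$tpr) >= 0))
})

test_that("AUC is invariant to monotone transforms and flips under label swap", {
  set.seed(31)
  probs <- runif(150); y <- rbinom(150, 1, probs)
  a <- roc_auc(probs, y)$auc
  expect_equal(roc_auc(qlogis(probs), y)$auc, a)      # strictly increasing
  expect_equal(roc_auc(probs, 1 - y)$auc, 1 - a)
  expect_error(roc_auc(probs, rep(1, 150)), "degenerate")
})

test_that("Hanley-McNeil SE matches a direct transcription of the formula", {
  set.seed(55)
  probs <- runif(300); y <- rbinom(300, 1, probs)
  r <- roc_auc(probs, y)
  a <- r$auc; m <- r$n_pos; n <- r$n_neg
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  expect_equal(r$se, sqrt((a * (1 - a) + (m - 1) * (q1 - a^2) +
                           (n - 1) * (q2 - a^2)) / (m * n)))
})

test_that("the cut-off maximises Youden's J and lands mid-gap", {
  # perfect separation: the gap is (0.2, 0.8), midpoint 0.5
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(roc_cutoff(r), 0.5)
  # brute-force scan oracle on simulated scores
  set.seed(77)
  probs <- round(runif(500), 2)
  y <- rbinom(500, 1, plogis(5 * probs - 2.5))
  cut <- roc_cutoff(roc_auc(probs, y))
  j_at <- vapply(sort(unique(probs)), function(t)
    oracle_youden_j(probs, y, t), numeric(1))
  expect_equal(oracle_youden_j(probs, y, cut), max(j_at), tolerance = 1e-12)
  # ties break toward the higher-specificity (higher) threshold
  r2 <- roc_auc(c(0.8, 0.6, 0.4, 0.2), c(1, 0, 1, 0))
  # J = 0.5 at thresholds 0.8 and 0.4; pick 0.8, midpoint with 0.6 is 0.7
  expect_equal(roc_cutoff(r2), 0.7)
})

test_that("classification tables compute DOR and percent correct", {
  probs <- c(rep(0.9, 80), rep(0.1, 20), rep(0.9, 20), rep(0.1, 80))
  y <- rep(c(1, 0), c(100, 100))
  ct <- classification_table(probs, y, 0.5)
  expect_equal(c(ct$tp, ct$fn, ct$fp, ct$tn), c(80, 20, 20, 80))
  expect_equal(ct$sensitivity, 0.8)
  expect_equal(ct$specificity, 0.8)
  expect_equal(ct$dor, 16)
  expect_equal(ct$pct_correct, 80)
  expect_equal(ct$tp + ct$fp + ct$tn + ct$fn, 200)
  # cutoff below every score: everything called positive
  ct2 <- suppressWarnings(classification_table(probs, y, 0.01))
  expect_equal(ct2$sensitivity, 1)
  expect_equal(ct2$specificity, 0)
  expect_warning(classification_table(probs, y, 0.01), "zero cell")
  ct3 <- classification_table(probs, y, 0.01, continuity = TRUE)
  expect_true(is.finite(ct3$dor))
})

test_that("quintile calibration splits near-equally and recovers constants", {
  # constant probability with Bernoulli outcomes: every bin predicts p
  set.seed(12)
  cal <- calibration_quintiles(rep(0.3, 1000), rbinom(1000, 1, 0.3))
  expect_equal(cal$mean_predicted, rep(0.3, 5))
  expect_equal(cal$n, rep(200L, 5))
  # n = 5 boundary: one record per bin
  cal5 <- calibration_quintiles(seq(0.1, 0.5, 0.1), c(0, 0, 1, 0, 1))
  expect_equal(cal5$n, rep(1L, 5))
  expect_equal(cal5$mean_predicted, seq(0.1, 0.5, 0.1))
  # remainder goes to the lowest bins
  cal7 <- calibration_quintiles(seq_len(7) / 10, rep(0, 7))
  expect_equal(cal7$n, c(2L, 2L, 1L, 1L, 1L))
  expect_error(calibration_quintiles(c(0.1, 0.2), c(0, 1)), "at least 5")
})

test_that("DerSimonian-Laird pooling matches a hand-computed oracle", {
  # frozen values computed independently from the textbook formulas
  m <- meta_auc(auc = c(0.80, 0.84, 0.86, 0.90, 0.78),
                se = c(0.02, 0.015, 0.03, 0.025, 0.01))
  expect_equal(m$pooled, 0.8323846315426005, tolerance = 1e-10)
  expect_equal(m$tau2, 0.0019142444658325297, tolerance = 1e-10)
  expect_equal(m$i2, 0.8619957353119636, tolerance = 1e-10)
  expect_equal(m$q, 28.9846115193769, tolerance = 1e-10)
  expect_equal(m$ci_low, 0.7900674840106789, tolerance = 1e-10)
  expect_equal(m$ci_high, 0.874701779074522, tolerance = 1e-10)
  expect_equal(sum(m$studies$weight), 1)
})

test_that("meta-analysis degenerate and homogeneous cases behave", {
  one <- meta_auc(0.84, 0.01)
  expect_equal(one$pooled, 0.84)
  expect_equal(one$tau2, 0)
  same <- meta_auc(rep(0.85, 4), rep(0.02, 4))
  expect_equal(same$pooled, 0.85)
  expect_equal(same$tau2, 0)
  expect_equal(same$i2, 0)
  # pooled estimate stays inside the study range
  set.seed(9)
  for (i in 1:10) {
    a <- runif(6, 0.6, 0.95); s <- runif(6, 0.005, 0.05)
    m <- meta_auc(a, s)
    expect_gte(m$pooled, min(a)); expect_lte(m$pooled, max(a))
  }
  expect_error(meta_auc(numeric(0), numeric(0)), "no studies")
  # data.frame interface with study ids
  df <- data.frame(study_id = c("a", "b"), auc = c(0.8, 0.9),
                   se = c(0.02, 0.02))
  expect_equal(meta_auc(df)$studies$study_id, c("a", "b"))
})

test_that("validate_model wires prediction into ROC, cut-off, table and calibration", {
  ds <- simulate_deliveries(sim_config(n_facilities = 3L,
                                       n_per_facility = 1500L, seed = 101L))
  v <- validate_model(ds, version = "v1.0")
  expect_equal(v$version, "v1.0")
  expect_gt(v$roc$auc, 0.7)     # the model should discriminate on its own data
  expect_true(v$cutoff > 0 && v$cutoff < 1)
  expect_equal(v$classification$tp + v$classification$fp +
               v$classification$tn + v$classification$fn, v$n_used)
  expect_equal(nrow(v$calibration), 5L)
})
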