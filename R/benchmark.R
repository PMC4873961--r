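# Observed-vs-expected benchmarking of facility CS rates.
#
# The expected CS rate of a dataset is the mean model probability over its
# records - a case-mix adjusted benchmark. The standardised caesarean section
# ratio (SCR) is observed / expected (equivalently observed CS count over the
# sum of predicted probabilities). An uncertainty range of +/-20% (relative,
# configurable) around the expected rate flags facilities whose observed rate
# falls outside what their case mix would predict.

.benchmark_core <- function(prob, observed_cs, version, range) {
  n_pred <- length(prob)
  expected <- 100 * sum(prob) / n_pred
  observed <- 100 * sum(observed_cs) / n_pred
  if (expected == 0) stop("expected rate is zero; standardised CS ratio undefined")
  lo <- (1 - range) * expected
  hi <- (1 + range) * expected
  flag <- if (observed < lo) "below_range" else
    if (observed > hi) "above_range" else "within_range"
  structure(list(
    n_predicted = n_pred, version = version,
    observed_rate = observed, expected_rate = expected,
    uncertainty_low = lo, uncertainty_high = hi,
    deviation = observed - expected,
    scr = observed / expected,
    flag = flag), class = "benchmark_report")
}

#' Benchmark a facility's CS rate against its case-mix expectation
#'
#' Computes the observed CS rate, the model-expected rate, their deviation
#' (percentage points), the standardised CS ratio and the uncertainty range.
#' Records that cannot be predicted (missing covariates) or lack a recorded
#' mode of delivery are excluded from BOTH the observed and the expected
#' rate, so the two are computed over the identical record subset; the
#' exclusion count is always reported. An expected rate above or below range
#' is a trigger for further inquiry into practice or data, not a verdict.
#'
#' @param ds A `facility_dataset` with mode_of_delivery recorded.
#' @param version `"auto"` or a fixed version id.
#' @param age_cutoff Maternal-age cutoff for x7 (years, default 35).
#' @param range Relative half-width of the uncertainty band around the
#'   expected rate (default 0.20).
#' @return A `benchmark_report`: list with `n_total`, `n_predicted`,
#'   `n_excluded`, `version`, `observed_rate`, `expected_rate`,
#'   `uncertainty_low`, `uncertainty_high`, `deviation` (observed - expected,
#'   percentage points), `scr`, `flag` (within/above/below_range).
#' @export
cs_benchmark <- function(ds, version = "auto", age_cutoff = 35, range = 0.20) {
  stopifnot(inherits(ds, "facility_dataset"), range > 0, range < 1)
  r <- ds$records
  has_mode <- !is.na(r$mode_of_delivery)
  if (!any(has_mode)) stop("no records with a recorded mode of delivery")
  preds <- predict_dataset(ds, version = version, age_cutoff = age_cutoff)
  use <- has_mode & !is.na(preds$probability)
  if (!any(use)) stop("no records both predictable and with recorded outcome")
  rep <- .benchmark_core(preds$probability[use],
                         r$mode_of_delivery[use] == "caesarean",
                         attr(preds, "version"), range)
  rep$n_total <- nrow(r)
  rep$n_excluded <- nrow(r) - rep$n_predicted
  rep
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> version %s, %d/%d records used\n",
              x$version, x$n_predicted,
              if (is.null(x$n_total)) x$n_predicted else x$n_total))
  cat(sprintf("  observed %.1f%%  expected %.1f%% (range %.1f-%.1f%%)\n",
              x$observed_rate, x$expected_rate,
              x$uncertainty_low, x$uncertainty_high))
  cat(sprintf("  deviation %+.1f pp   standardised CS ratio %.2f   [%s]\n",
              x$deviation, x$scr, x$flag))
  invisible(x)
}

#' Benchmark within each Robson group
#'
#' Runs the benchmark of [cs_benchmark()] separately inside each Robson
#' group. Groups with fewer than `min_n` predictable records are flagged
#' `low_n` and not reported (group-level rates on a handful of deliveries
#' are noise).
#'
#' @inheritParams cs_benchmark
#' @param min_n Minimum predictable records per group (default 20).
#' @return Named list over groups `"1"`..`"10"`: each element a
#'   `benchmark_report`, the string `"low_n"`, or `"empty"`.
#' @export
cs_benchmark_by_group <- function(ds, version = "auto", age_cutoff = 35,
                                  range = 0.20, min_n = 20L) {
  stopifnot(inherits(ds, "facility_dataset"))
  r <- ds$records
  vid <- if (identical(version, "auto")) best_version(ds) else
    .as_model_version(version)$id
  preds <- predict_dataset(ds, version = vid, age_cutoff = age_cutoff)
  g <- robson_classify(ds)
  use <- !is.na(r$mode_of_delivery) & !is.na(preds$probability) & !is.na(g)
  out <- stats::setNames(vector("list", 10L), as.character(1:10))
  for (k in 1:10) {
    idx <- use & g == k
    if (!any(idx)) { out[[as.character(k)]] <- "empty"; next }
    if (sum(idx) < min_n) { out[[as.character(k)]] <- "low_n"; next }
    rep <- .benchmark_core(preds$probability[idx],
                           r$mode_of_delivery[idx] == "caesarean",
                           vid, range)
    rep$n_total <- sum(g == k, na.rm = TRUE)
    rep$n_excluded <- rep$n_total - rep$n_predicted
    out[[as.character(k)]] <- rep
  }
  out
}
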