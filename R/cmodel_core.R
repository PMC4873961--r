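# The four published logistic scoring models for the individual probability
# of caesarean section, and the covariate encoding they share.
#
# Each version is a fixed intercept + coefficient set over up to fourteen
# encoded covariates x1..x14. The versions differ only in which covariates
# they use, so a facility applies the richest version its data can support:
#   v1.0  x1-x6   obstetric characteristics only
#   v1.1  + x7    maternal age indicator
#   v1.2  + x8    organ dysfunction / ICU admission
#   v1.3  x1-x5, x7-x14 (drops preterm, adds six complications)
# The shipped coefficients are reproduced verbatim from the published table
# and are asserted character-for-character by the test suite.

.cmodel_coefficients <- list(
  "v1.0" = c("(Intercept)" = -3.392134,
             x1 = -0.559968, x2 = 2.842534, x3 = 1.694844,
             x4 = 2.747953, x5 = 2.922391, x6 = 0.368073),
  "v1.1" = c("(Intercept)" = -3.992549,
             x1 = -0.760441, x2 = 2.873179, x3 = 1.722743,
             x4 = 2.708164, x5 = 2.911992, x6 = 0.364223,
             x7 = 0.734265),
  "v1.2" = c("(Intercept)" = -3.989357,
             x1 = -0.761730, x2 = 2.878130, x3 = 1.721366,
             x4 = 2.686502, x5 = 2.924100, x6 = 0.285275,
             x7 = 0.728236, x8 = 1.499462),
  "v1.3" = c("(Intercept)" = -4.015252,
             x1 = -0.775310, x2 = 2.922222, x3 = 1.834027,
             x4 = 2.634921, x5 = 2.985162,
             x7 = 0.711040, x8 = 0.661417, x9 = 3.796513,
             x10 = 2.741255, x11 = 0.561991, x12 = 0.987180,
             x13 = 1.301346, x14 = 1.310211)
)

# record field feeding each covariate index
.covariate_fields <- c(
  x1 = "parity", x2 = "previous_cs", x3 = "multiple_pregnancy",
  x4 = "onset_of_labour", x5 = "presentation", x6 = "gestational_age",
  x7 = "maternal_age", x8 = "organ_dysfunction_or_icu",
  x9 = "placenta_praevia", x10 = "abruptio_placentae",
  x11 = "chronic_hypertension", x12 = "preeclampsia_level",
  x13 = "renal_disease", x14 = "hiv"
)

.covariate_labels <- c(
  x1 = "parity (1 = multiparous)", x2 = "previous caesarean section",
  x3 = "multiple pregnancy", x4 = "provider-initiated childbirth",
  x5 = "presentation (0 cephalic / 1 breech / 2 transverse or other)",
  x6 = "preterm birth (<= 36 weeks)",
  x7 = "maternal age at or above cutoff",
  x8 = "organ dysfunction or ICU admission",
  x9 = "placenta praevia", x10 = "abruptio placentae",
  x11 = "chronic hypertension",
  x12 = "pre-eclampsia (1) / eclampsia (2)",
  x13 = "renal disease", x14 = "HIV"
)

#' The shipped scoring-model versions
#'
#' @param id Optional version id (`"v1.0"`, `"v1.1"`, `"v1.2"`, `"v1.3"`).
#' @return With `id`, one `model_version` (list: `id`, `intercept`,
#'   `coefficients` named by covariate index, `covariates`, `fields` the
#'   record fields required). Without, the list of all four.
#' @export
cmodel_versions <- function(id = NULL) {
  build <- function(v) {
    beta <- .cmodel_coefficients[[v]]
    covs <- setdiff(names(beta), "(Intercept)")
    structure(list(id = v, intercept = unname(beta[["(Intercept)"]]),
                   coefficients = beta[covs], covariates = covs,
                   fields = unname(.covariate_fields[covs])),
              class = "model_version")
  }
  if (is.null(id)) {
    return(stats::setNames(lapply(names(.cmodel_coefficients), build),
                           names(.cmodel_coefficients)))
  }
  if (!id %in% names(.cmodel_coefficients)) {
    stop("unknown model version '", id, "'")
  }
  build(id)
}

#' @export
print.model_version <- function(x, ...) {
  cat(sprintf("<model_version %s> intercept %f\n", x$id, x$intercept))
  for (cv in x$covariates) {
    cat(sprintf("  %-4s %+f  %s\n", cv, x$coefficients[[cv]],
                .covariate_labels[[cv]]))
  }
  invisible(x)
}

.as_model_version <- function(version) {
  if (inherits(version, "model_version")) return(version)
  cmodel_versions(version)
}

#' Encode records as model covariates x1..x14
#'
#' Encoding rules: a condition absent scores 0 and present scores 1, except
#' presentation (0 cephalic, 1 breech, 2 transverse/oblique or other) and
#' pre-eclampsia (0 none, 1 pre-eclampsia, 2 eclampsia). x1 is 1 for
#' multiparous women (parity >= 1); x2 is 1 for at least one previous CS;
#' x4 (provider-initiated childbirth) covers induced labour and prelabour
#' caesarean section alike; x6 is 1 for <= 36 completed weeks; x7 is 1 at or
#' above `age_cutoff`. A missing source field yields NA in that entry.
#'
#' The age cutoff is not part of the published coding rules; the default of
#' 35 years is the conventional advanced-maternal-age boundary and is
#' exposed as a parameter.
#'
#' @param x A `facility_dataset` or data.frame of records.
#' @param age_cutoff Years; x7 = 1 iff maternal_age >= cutoff. Default 35.
#' @return Numeric matrix, one row per record, columns x1..x14; NA marks a
#'   covariate underivable for that record.
#' @export
encode_covariates <- function(x, age_cutoff = 35) {
  r <- if (inherits(x, "facility_dataset")) x$records else
    facility_dataset(x)$records
  flag <- function(l) as.numeric(l)
  m <- cbind(
    x1 = as.numeric(r$parity >= 1L),
    x2 = as.numeric(r$previous_cs >= 1L),
    x3 = flag(r$multiple_pregnancy),
    x4 = as.numeric(r$onset_of_labour %in% c("induced", "prelabour_cs")),
    x5 = c(cephalic = 0, breech = 1, transverse_oblique = 2,
           other = 2)[r$presentation],
    x6 = as.numeric(r$gestational_age <= 36L),
    x7 = as.numeric(r$maternal_age >= age_cutoff),
    x8 = flag(r$organ_dysfunction_or_icu),
    x9 = flag(r$placenta_praevia),
    x10 = flag(r$abruptio_placentae),
    x11 = flag(r$chronic_hypertension),
    x12 = c(none = 0, preeclampsia = 1, eclampsia = 2)[r$preeclampsia_level],
    x13 = flag(r$renal_disease),
    x14 = flag(r$hiv)
  )
  # %in% returns FALSE for NA; restore missingness for x4
  m[is.na(r$onset_of_labour), "x4"] <- NA_real_
  rownames(m) <- r$record_id
  m
}

#' Linear predictor of a scoring-model version
#'
#' Intercept plus the dot product over the version's covariates, summed in
#' ascending covariate index so results are bit-stable across platforms.
#'
#' @param cov Numeric vector named x1..x14 (or any superset of the version's
#'   covariates), or a matrix as returned by [encode_covariates()].
#' @param version Version id or `model_version`.
#' @return Numeric logit(s). Errors if a required covariate is NA, naming the
#'   offending indices.
#' @export
cmodel_logit <- function(cov, version) {
  mv <- .as_model_version(version)
  if (is.null(dim(cov))) cov <- matrix(cov, nrow = 1,
                                       dimnames = list(NULL, names(cov)))
  need <- mv$covariates
  miss_col <- setdiff(need, colnames(cov))
  if (length(miss_col) > 0) {
    stop("covariate(s) not supplied: ", paste(miss_col, collapse = ", "))
  }
  sub <- cov[, need, drop = FALSE]
  if (anyNA(sub)) {
    bad <- need[colSums(is.na(sub)) > 0]
    stop(sprintf("incomplete record(s) under %s: missing %s", mv$id,
                 paste(bad, collapse = ", ")))
  }
  # ascending index order is the order of mv$coefficients
  out <- rep(mv$intercept, nrow(sub))
  for (cv in need) out <- out + sub[, cv] * mv$coefficients[[cv]]
  unname(out)
}

#' Probability of caesarean section
#'
#' The logistic transform of [cmodel_logit()]:
#' probability = exp(logit) / (1 + exp(logit)).
#'
#' @inheritParams cmodel_logit
#' @return Probability in (0, 1), strictly increasing in the logit.
#' @export
cmodel_probability <- function(cov, version) {
  stats::plogis(cmodel_logit(cov, version))
}

#' Richest model version supported by the available fields
#'
#' The version with the largest number of covariates whose source fields are
#' all present gives the best case-mix adjustment, so version selection walks
#' v1.3, v1.2, v1.1, v1.0 and returns the first fully derivable one.
#'
#' @param manifest Character vector of populated field names, or a
#'   `facility_dataset` (its manifest is used).
#' @return Version id string. Errors if even the v1.0 fields are incomplete,
#'   listing what is missing.
#' @export
best_version <- function(manifest) {
  if (inherits(manifest, "facility_dataset")) manifest <- manifest$manifest
  v10 <- cmodel_versions("v1.0")
  missing10 <- setdiff(v10$fields, manifest)
  if (length(missing10) > 0) {
    stop("no model version applicable; v1.0 requires missing field(s): ",
         paste(missing10, collapse = ", "))
  }
  for (v in c("v1.3", "v1.2", "v1.1", "v1.0")) {
    if (all(cmodel_versions(v)$fields %in% manifest)) return(v)
  }
  "v1.0"
}

#' Predict CS probabilities for every record of a dataset
#'
#' Every record complete under the chosen version gets a probability; records
#' with a missing required covariate are excluded with a reason naming the
#' missing indices. Counts are preserved: predicted + excluded = n.
#'
#' @param ds A `facility_dataset`.
#' @param version `"auto"` (default; resolves via [best_version()]) or a
#'   fixed version id.
#' @param age_cutoff Passed to [encode_covariates()].
#' @return A `cmodel_predictions` data.frame with columns `record_id`,
#'   `version`, `probability` (NA when excluded), `excluded_reason` (NA when
#'   predicted); attribute `version` holds the resolved id.
#' @export
predict_dataset <- function(ds, version = "auto", age_cutoff = 35) {
  stopifnot(inherits(ds, "facility_dataset"))
  vid <- if (identical(version, "auto")) best_version(ds) else
    .as_model_version(version)$id
  mv <- cmodel_versions(vid)
  cov <- encode_covariates(ds, age_cutoff = age_cutoff)
  sub <- cov[, mv$covariates, drop = FALSE]
  nmiss <- is.na(sub)
  complete <- rowSums(nmiss) == 0L
  if (!any(complete)) {
    stop("no record is complete under ", vid)
  }
  prob <- rep(NA_real_, nrow(sub))
  prob[complete] <- cmodel_probability(sub[complete, , drop = FALSE], mv)
  reason <- rep(NA_character_, nrow(sub))
  if (any(!complete)) {
    reason[!complete] <- apply(nmiss[!complete, , drop = FALSE], 1, function(z) {
      paste("missing", paste(mv$covariates[z], collapse = ","))
    })
  }
  out <- data.frame(record_id = ds$records$record_id,
                    version = vid,
                    probability = prob,
                    excluded_reason = reason,
                    stringsAsFactors = FALSE)
  attr(out, "version") <- vid
  class(out) <- c("cmodel_predictions", "data.frame")
  out
}
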