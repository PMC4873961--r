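# Synthetic multi-facility obstetric data with known truth.
#
# The generator draws covariates per-woman from configurable prevalences
# (independently, except for two consistency constraints: previous CS only
# for multiparous women, and prelabour-CS onset only for caesarean births),
# computes each woman's true CS probability under a chosen scoring-model
# version (optionally shifted by a normal per-facility logit effect), and
# draws the mode of delivery from that probability. Outcome flags are drawn
# at configured population rates. Everything is reproducible from the seed.
#
# Default prevalences are chosen so that the Robson relative group sizes of
# a large simulated dataset approximate those of a multi-country low-CS
# reference population (about 29% group 1, 40% group 3, 7% group 5, ~1%
# multiple pregnancies, ~0.4% transverse lie, ~4% preterm singletons).

#' Simulation configuration
#'
#' @param n_facilities Number of facilities.
#' @param n_per_facility Women per facility (scalar, or length-2 range
#'   sampled uniformly per facility).
#' @param prevalence Named list of covariate prevalences, each in [0, 1]:
#'   `multiparous`, `previous_cs_given_multiparous`, `provider_initiated`,
#'   `breech`, `transverse_oblique`, `multiple_pregnancy`, `preterm`,
#'   `age_over_cutoff`, `organ_dysfunction`, `placenta_praevia`,
#'   `abruptio_placentae`, `chronic_hypertension`, `preeclampsia`,
#'   `eclampsia`, `renal_disease`, `hiv`. Omitted entries keep defaults.
#' @param truth_version Version whose coefficients generate the outcome
#'   (default `"v1.0"`).
#' @param truth_coefficients Optional named vector overriding the shipped
#'   coefficients (must include `"(Intercept)"` and the version covariates).
#' @param facility_effect_sd SD of the per-facility normal shift on the logit
#'   scale (default 0, so a fixed-effects refit is well-specified).
#' @param intrapartum_mortality_per_1000 Intrapartum-related perinatal deaths
#'   per 1000 births (split evenly between intrapartum stillbirths and day-1
#'   neonatal deaths). Default 3.0.
#' @param maternal_mortality_per_100000 Default 23.6.
#' @param near_miss_per_1000 Default 2.6.
#' @param age_cutoff Maternal-age cutoff (years) used in encoding and in the
#'   age draw (default 35).
#' @param seed Integer RNG seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_facilities = 10L, n_per_facility = 500L,
                       prevalence = list(), truth_version = "v1.0",
                       truth_coefficients = NULL, facility_effect_sd = 0,
                       intrapartum_mortality_per_1000 = 3.0,
                       maternal_mortality_per_100000 = 23.6,
                       near_miss_per_1000 = 2.6,
                       age_cutoff = 35, seed) {
  if (missing(seed)) stop("seed is mandatory")
  prev <- list(
    multiparous = 0.59, previous_cs_given_multiparous = 0.133,
    provider_initiated = 0.18, breech = 0.027, transverse_oblique = 0.004,
    multiple_pregnancy = 0.009, preterm = 0.044, age_over_cutoff = 0.09,
    organ_dysfunction = 0.003, placenta_praevia = 0.005,
    abruptio_placentae = 0.010, chronic_hypertension = 0.005,
    preeclampsia = 0.025, eclampsia = 0.003, renal_disease = 0.004,
    hiv = 0.010)
  unknown <- setdiff(names(prevalence), names(prev))
  if (length(unknown) > 0) {
    stop("unknown prevalence name(s): ", paste(unknown, collapse = ", "))
  }
  prev[names(prevalence)] <- prevalence
  bad <- vapply(prev, function(p) !is.numeric(p) || p < 0 || p > 1, logical(1))
  if (any(bad)) stop("prevalences must lie in [0, 1]: ",
                     paste(names(prev)[bad], collapse = ", "))
  if (prev$breech + prev$transverse_oblique > 1) {
    stop("breech + transverse_oblique prevalence exceeds 1")
  }
  if (prev$preeclampsia + prev$eclampsia > 1) {
    stop("preeclampsia + eclampsia prevalence exceeds 1")
  }
  mv <- cmodel_versions(truth_version)
  if (!is.null(truth_coefficients)) {
    need <- c("(Intercept)", mv$covariates)
    if (!all(need %in% names(truth_coefficients))) {
      stop("truth_coefficients must name ", paste(need, collapse = ", "))
    }
  }
  structure(list(
    n_facilities = as.integer(n_facilities),
    n_per_facility = as.integer(n_per_facility),
    prevalence = prev, truth_version = truth_version,
    truth_coefficients = truth_coefficients,
    facility_effect_sd = facility_effect_sd,
    intrapartum_mortality_per_1000 = intrapartum_mortality_per_1000,
    maternal_mortality_per_100000 = maternal_mortality_per_100000,
    near_miss_per_1000 = near_miss_per_1000,
    age_cutoff = age_cutoff, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a multi-facility obstetric dataset
#'
#' See [sim_config()] for the generative model. The true per-woman CS
#' probability is recorded in the attribute `"true_probability"` of the
#' returned dataset so calibration and recovery tests can compare against
#' the exact truth.
#'
#' @param config A `sim_config`.
#' @return A `facility_dataset` passing [validate_dataset()] with zero
#'   violations; attribute `"true_probability"` holds the generating
#'   probabilities.
#' @export
simulate_deliveries <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  pr <- config$prevalence
  nf <- config$n_facilities
  npf <- if (length(config$n_per_facility) == 2L) {
    sample(config$n_per_facility[1]:config$n_per_facility[2], nf,
           replace = TRUE)
  } else rep(config$n_per_facility, nf)
  n <- sum(npf)
  fac <- rep(sprintf("fac%02d", seq_len(nf)), times = npf)
  fac_effect <- rep(stats::rnorm(nf, 0, config$facility_effect_sd),
                    times = npf)

  multip <- stats::runif(n) < pr$multiparous
  parity <- ifelse(multip, pmin(1L + stats::rgeom(n, 0.55), 8L), 0L)
  prevcs_flag <- multip & (stats::runif(n) < pr$previous_cs_given_multiparous)
  previous_cs <- ifelse(prevcs_flag,
                        ifelse(stats::runif(n) < 0.85, 1L, 2L), 0L)
  u <- stats::runif(n)
  presentation <- ifelse(u < pr$transverse_oblique, "transverse_oblique",
                  ifelse(u < pr$transverse_oblique + pr$breech, "breech",
                         "cephalic"))
  multiple <- stats::runif(n) < pr$multiple_pregnancy
  preterm <- stats::runif(n) < pr$preterm
  gestational_age <- ifelse(preterm, sample(30:36, n, replace = TRUE),
                            sample(37:41, n, replace = TRUE,
                                   prob = c(0.1, 0.2, 0.35, 0.25, 0.1)))
  provider <- stats::runif(n) < pr$provider_initiated
  onset <- ifelse(provider, "induced", "spontaneous")
  aged <- stats::runif(n) < pr$age_over_cutoff
  cut <- config$age_cutoff
  maternal_age <- ifelse(aged, sample(cut:(cut + 9), n, replace = TRUE),
                         sample(16:(cut - 1), n, replace = TRUE))
  u2 <- stats::runif(n)
  preeclampsia_level <- ifelse(u2 < pr$eclampsia, "eclampsia",
                        ifelse(u2 < pr$eclampsia + pr$preeclampsia,
                               "preeclampsia", "none"))
  rec <- data.frame(
    record_id = sprintf("w%06d", seq_len(n)),
    facility_id = fac,
    country_id = sprintf("country%d", ((match(fac, unique(fac)) - 1L) %/% 5L) + 1L),
    maternal_age = as.integer(maternal_age),
    parity = as.integer(parity),
    previous_cs = as.integer(previous_cs),
    onset_of_labour = onset,
    gestational_age = as.integer(gestational_age),
    presentation = presentation,
    multiple_pregnancy = multiple,
    organ_dysfunction_or_icu = stats::runif(n) < pr$organ_dysfunction,
    placenta_praevia = stats::runif(n) < pr$placenta_praevia,
    abruptio_placentae = stats::runif(n) < pr$abruptio_placentae,
    chronic_hypertension = stats::runif(n) < pr$chronic_hypertension,
    renal_disease = stats::runif(n) < pr$renal_disease,
    hiv = stats::runif(n) < pr$hiv,
    preeclampsia_level = preeclampsia_level,
    stringsAsFactors = FALSE)

  mv <- cmodel_versions(config$truth_version)
  beta <- if (is.null(config$truth_coefficients)) {
    c("(Intercept)" = mv$intercept, mv$coefficients)
  } else config$truth_coefficients
  cov <- encode_covariates(rec, age_cutoff = config$age_cutoff)
  eta <- rep(unname(beta[["(Intercept)"]]), n)
  for (cv in mv$covariates) eta <- eta + cov[, cv] * unname(beta[[cv]])
  p_true <- stats::plogis(eta + fac_effect)
  cs <- stats::runif(n) < p_true
  rec$mode_of_delivery <- ifelse(cs, "caesarean", "vaginal")
  # some provider-initiated caesareans happened before labour
  prelab <- provider & cs & stats::runif(n) < 0.5
  rec$onset_of_labour[prelab] <- "prelabour_cs"

  death <- stats::runif(n) < config$intrapartum_mortality_per_1000 / 1000
  stillb <- death & stats::runif(n) < 0.5
  rec$intrapartum_stillbirth <- stillb
  rec$neonatal_death_day1 <- death & !stillb
  rec$livebirth <- !stillb
  rec$maternal_death <- stats::runif(n) < config$maternal_mortality_per_100000 / 1e5
  rec$maternal_near_miss <- !rec$maternal_death &
    stats::runif(n) < config$near_miss_per_1000 / 1000

  ds <- facility_dataset(rec, provenance = sprintf("simulated (seed %d)",
                                                   config$seed))
  attr(ds, "true_probability") <- p_true
  ds
}

# one hand-written record per Robson group (1..10); complication flags off
.fixture_template <- function() {
  data.frame(
    parity          = c(0L, 0L, 2L, 1L, 1L, 0L, 2L, 1L, 0L, 0L),
    previous_cs     = c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 1L, 0L, 0L),
    onset_of_labour = c("spontaneous", "induced", "spontaneous", "induced",
                        "spontaneous", "spontaneous", "spontaneous",
                        "spontaneous", "spontaneous", "spontaneous"),
    gestational_age = c(39L, 40L, 39L, 38L, 39L, 39L, 38L, 38L, 39L, 34L),
    presentation    = c("cephalic", "cephalic", "cephalic", "cephalic",
                        "cephalic", "breech", "breech", "cephalic",
                        "transverse_oblique", "cephalic"),
    multiple_pregnancy = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                           TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Named test fixtures
#'
#' \describe{
#'   \item{tiny}{12 hand-written records: one per Robson group plus two
#'     unclassifiable (missing gestational age; missing presentation).}
#'   \item{table2_like}{A dataset whose per-group sizes and CS counts exactly
#'     reconstruct the printed margins of the reference population's Robson
#'     table (41,203 classified births, overall CS rate 18.5%, plus 1,434
#'     records with missing gestational age). All records are synthetic
#'     archetypes, not source data.}
#'   \item{heterogeneous_facilities}{20 facilities x 150 women spanning CS
#'     rates 5-50% and intrapartum mortality 1-12 per 1000, for
#'     reference-selection tests.}
#' }
#'
#' @param name One of `"tiny"`, `"table2_like"`,
#'   `"heterogeneous_facilities"`.
#' @return A `facility_dataset`.
#' @export
make_fixture <- function(name = c("tiny", "table2_like",
                                  "heterogeneous_facilities")) {
  name <- match.arg(name)
  tmpl <- .fixture_template()
  if (name == "tiny") {
    rec <- tmpl
    rec$maternal_age <- 28L
    rec$organ_dysfunction_or_icu <- FALSE
    rec$mode_of_delivery <- c("vaginal", "caesarean", "vaginal", "vaginal",
                              "caesarean", "caesarean", "caesarean",
                              "caesarean", "caesarean", "vaginal")
    u1 <- rec[1, ]; u1$gestational_age <- NA_integer_
    u2 <- rec[1, ]; u2$presentation <- NA_character_
    rec <- rbind(rec, u1, u2)
    rec$mode_of_delivery[11:12] <- "vaginal"
    rec$record_id <- sprintf("tiny%02d", 1:12)
    rec$facility_id <- "fac01"
    rec$livebirth <- TRUE
    rec$intrapartum_stillbirth <- FALSE
    return(facility_dataset(rec, provenance = "fixture:tiny"))
  }
  if (name == "table2_like") {
    sizes <- c(12069L, 3620L, 16538L, 2631L, 2948L, 498L, 638L, 385L, 158L,
               1718L)
    cs <- c(1182L, 1446L, 503L, 624L, 2194L, 391L, 471L, 222L, 140L, 432L)
    rows <- lapply(1:10, function(g) {
      r <- tmpl[rep(g, sizes[g]), , drop = FALSE]
      r$mode_of_delivery <- rep(c("caesarean", "vaginal"),
                                c(cs[g], sizes[g] - cs[g]))
      r
    })
    rec <- do.call(rbind, rows)
    miss <- tmpl[rep(1L, 1434L), , drop = FALSE]
    miss$gestational_age <- NA_integer_
    miss$mode_of_delivery <- "vaginal"
    rec <- rbind(rec, miss)
    rec$record_id <- sprintf("t2_%05d", seq_len(nrow(rec)))
    rec$facility_id <- "facA"
    return(facility_dataset(rec, provenance = "fixture:table2_like"))
  }
  # heterogeneous_facilities
  nfac <- 20L; npf <- 150L
  cs_rate <- seq(0.05, 0.50, length.out = nfac)
  mort <- seq(1, 12, length.out = nfac)          # per 1000 livebirths
  rows <- lapply(seq_len(nfac), function(i) {
    r <- .fixture_template()[rep(1L, npf), , drop = FALSE]
    ncs <- round(cs_rate[i] * npf)
    r$mode_of_delivery <- rep(c("caesarean", "vaginal"), c(ncs, npf - ncs))
    ndeath <- round(mort[i] * npf / 1000)
    r$neonatal_death_day1 <- rep(c(TRUE, FALSE), c(ndeath, npf - ndeath))
    r$intrapartum_stillbirth <- FALSE
    r$livebirth <- TRUE
    r$facility_id <- sprintf("fac%02d", i)
    r
  })
  rec <- do.call(rbind, rows)
  rec$record_id <- sprintf("het%04d", seq_len(nrow(rec)))
  facility_dataset(rec, provenance = "fixture:heterogeneous_facilities")
}
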