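# Facility indicators, double-median reference selection, 90/10 split,
# and the from-scratch logistic fitter.

make_counts_facility <- function(facility_id, n_livebirths, n_stillbirths,
                                 n_day1_deaths, n_maternal_deaths,
                                 n_cs, n_near_miss = 0L) {
  n <- n_livebirths + n_stillbirths
  rec <- data.frame(
    record_id = sprintf("%s_%06d", facility_id, seq_len(n)),
    facility_id = facility_id,
    mode_of_delivery = rep(c("caesarean", "vaginal"), c(n_cs, n - n_cs)),
    livebirth = rep(c(FALSE, TRUE), c(n_stillbirths, n_livebirths)),
    intrapartum_stillbirth = rep(c(TRUE, FALSE), c(n_stillbirths,
                                                   n_livebirths)),
    neonatal_death_day1 = c(rep(FALSE, n_stillbirths),
                            rep(c(TRUE, FALSE),
                                c(n_day1_deaths,
                                  n_livebirths - n_day1_deaths))),
    maternal_death = rep(c(TRUE, FALSE), c(n_maternal_deaths,
                                           n - n_maternal_deaths)),
    maternal_near_miss = rep(c(FALSE, TRUE, FALSE),
                             c(n_maternal_deaths, n_near_miss,
                               n - n_maternal_deaths - n_near_miss)),
    stringsAsFactors = FALSE)
  facility_dataset(rec)
}

test_that("facility indicators reproduce the printed reference-population rates", {
  # 42,361 livebirths; 127 intrapartum-related deaths (stillbirths + day-1
  # neonatal deaths); 10 maternal deaths; 7,629 caesarean sections
  ds <- make_counts_facility("ref", n_livebirths = 42361L,
                             n_stillbirths = 60L, n_day1_deaths = 67L,
                             n_maternal_deaths = 10L, n_cs = 7629L,
                             n_near_miss = 111L)
  ind <- facility_indicators(ds)
  expect_equal(round(ind$intrapartum_perinatal_mortality, 1), 3.0)
  expect_equal(round(ind$maternal_mortality, 1), 23.6)
  expect_equal(round(ind$near_miss_rate, 1), 2.6)
  expect_equal(round(ind$severe_maternal_outcome_rate, 1), 2.9)
  expect_equal(round(ind$cs_rate, 1), 18.0)   # 7629/42421 women
  expect_equal(ind$n_livebirths, 42361L)
  expect_false(ind$flagged)
})

test_that("zero-death and zero-livebirth facilities are handled", {
  ds <- make_counts_facility("ok", 500L, 0L, 0L, 0L, 50L)
  ind <- facility_indicators(ds)
  expect_equal(ind$intrapartum_perinatal_mortality, 0)
  # a facility of stillbirths only has undefined per-livebirth indicators
  rec <- data.frame(record_id = c("a", "b"), facility_id = "empty",
                    livebirth = FALSE, intrapartum_stillbirth = TRUE,
                    mode_of_delivery = "vaginal", stringsAsFactors = FALSE)
  ind2 <- facility_indicators(facility_dataset(rec))
  expect_true(is.na(ind2$intrapartum_perinatal_mortality))
  expect_true(ind2$flagged)
})

test_that("double-median selection takes facilities strictly below both thresholds", {
  ind <- data.frame(facility_id = as.character(1:4),
                    cs_rate = c(10, 20, 30, 40),
                    intrapartum_perinatal_mortality = c(1, 2, 3, 4))
  sel <- select_reference(ind)
  expect_equal(sel$cs_rate_threshold, 25)
  expect_equal(sel$mortality_threshold, 2.5)
  expect_equal(sel$selected, c("1", "2"))
  # anti-correlated indicators select nobody below both medians
  ind$intrapartum_perinatal_mortality <- c(4, 3, 2, 1)
  expect_equal(suppressWarnings(select_reference(ind)$selected),
               character(0))
  # identical facilities: nothing strictly below the median, with a warning
  same <- data.frame(facility_id = as.character(1:3), cs_rate = 20,
                     intrapartum_perinatal_mortality = 3)
  expect_warning(sel3 <- select_reference(same), "empty")
  expect_equal(sel3$selected, character(0))
  expect_error(select_reference(same[1, ]), "at least 2")
  # invariant to facility ordering
  ind2 <- data.frame(facility_id = as.character(1:9),
                     cs_rate = c(12, 35, 8, 22, 40, 15, 28, 18, 31),
                     intrapartum_perinatal_mortality =
                       c(2, 8, 1, 5, 9, 2.5, 6, 3, 7))
  perm <- ind2[sample(nrow(ind2)), ]
  expect_setequal(select_reference(ind2)$selected,
                  select_reference(perm)$selected)
})

test_that("the heterogeneous fixture yields a non-empty strict reference subset", {
  ds <- make_fixture("heterogeneous_facilities")
  sel <- select_reference(facility_indicators(ds))
  expect_gt(length(sel$selected), 0)
  expect_lt(length(sel$selected), 20)
})

test_that("split_reference partitions exactly, deterministically, by ceiling", {
  ds <- simulate_deliveries(sim_config(n_facilities = 2L,
                                       n_per_facility = 55L, seed = 2L))
  sp <- split_reference(ds, fraction = 0.9, seed = 17L)
  expect_equal(nrow(sp$a1$records), ceiling(0.9 * 110))
  expect_equal(nrow(sp$a2$records), 110 - ceiling(0.9 * 110))
  expect_setequal(c(sp$a1$records$record_id, sp$a2$records$record_id),
                  ds$records$record_id)
  expect_length(intersect(sp$a1$records$record_id,
                          sp$a2$records$record_id), 0)
  sp2 <- split_reference(ds, fraction = 0.9, seed = 17L)
  expect_equal(sp$a1$records$record_id, sp2$a1$records$record_id)
  # n = 10 at 0.9 -> 9/1
  small <- facility_dataset(ds$records[1:10, ])
  sp3 <- split_reference(small, seed = 4L)
  expect_equal(nrow(sp3$a1$records), 9L)
  expect_equal(nrow(sp3$a2$records), 1L)
})

test_that("the logistic fitter matches closed forms", {
  set.seed(61)
  # intercept-only: log odds of the event rate
  y <- rep(c(1, 0), c(30, 70))
  f <- fit_logistic(matrix(numeric(0), nrow = 100, ncol = 0), y)
  expect_equal(unname(f$coefficients), log(0.3 / 0.7), tolerance = 1e-8)
  expect_true(f$converged)
  # single binary covariate: coefficients equal the 2x2-table log odds
  x <- rep(c(0, 0, 1, 1), c(60, 20, 10, 30))
  y <- rep(c(0, 1, 0, 1), c(60, 20, 10, 30))
  f2 <- fit_logistic(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
  expect_equal(unname(f2$coefficients["(Intercept)"]), log(20 / 60),
               tolerance = 1e-8)
  expect_equal(unname(f2$coefficients["x"]), log(30 / 10) - log(20 / 60),
               tolerance = 1e-8)
  # SEs agree with glm's observed-information SEs
  g <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(unname(f2$se), unname(summary(g)$coefficients[, 2]),
               tolerance = 1e-6)
})

test_that("pathological designs raise the documented errors", {
  set.seed(62)
  x <- rnorm(50)
  y <- as.numeric(x > 0)                       # complete separation
  expect_error(fit_logistic(matrix(x, ncol = 1), y), "separation")
  X <- cbind(a = x, b = 2 * x)                 # collinear
  yy <- rbinom(50, 1, 0.5)
  expect_error(fit_logistic(X, yy), "singular|rank")
  expect_error(fit_logistic(matrix(1, 50, 1, dimnames = list(NULL, "c")),
                            yy), "constant")
  expect_error(fit_logistic(matrix(rnorm(4), 2, 2), c(0, 1)),
               "more observations")
})

test_that("refit on simulated truth recovers each coefficient within 3 SE", {
  ds <- simulate_deliveries(sim_config(n_facilities = 5L,
                                       n_per_facility = 3000L, seed = 88L))
  fit <- refit_cmodel(ds, version = "v1.0")
  mv <- cmodel_versions("v1.0")
  truth <- c("(Intercept)" = mv$intercept, mv$coefficients)
  expect_true(fit$converged)
  for (nm in names(truth)) {
    expect_lt(abs(fit$coefficients[[nm]] - truth[[nm]]), 3 * fit$se[[nm]])
  }
})
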