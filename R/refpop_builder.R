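# Reference-population construction and model (re)fitting.
#
# A reference population for benchmarking is drawn from facilities that show
# both low CS use and good intrapartum outcomes: facilities whose CS rate
# AND intrapartum-related perinatal mortality fall strictly below the
# across-facility medians. The selected population is split 90/10 into a
# model-building and a testing subset, and a from-scratch logistic ML fitter
# (IRLS) supports rebuilding the scoring model and parameter-recovery tests.

#' Per-facility outcome indicators
#'
#' Aggregates a multi-facility dataset into one row per facility:
#' number of women, livebirths, CS rate (% of women with recorded mode),
#' intrapartum-related perinatal mortality (intrapartum stillbirths plus
#' neonatal deaths on the first postpartum day, per 1000 livebirths),
#' maternal mortality (per 100,000 livebirths), maternal near-miss rate and
#' severe maternal outcome rate (near miss + maternal death, per 1000
#' livebirths). A facility with zero livebirths gets NA indicators and
#' `flagged = TRUE`.
#'
#' @param ds A `facility_dataset` with `facility_id`, `mode_of_delivery` and
#'   outcome flags populated.
#' @return Data.frame with one row per facility: `facility_id`, `n_women`,
#'   `n_livebirths`, `cs_rate`, `intrapartum_perinatal_mortality`,
#'   `maternal_mortality`, `near_miss_rate`, `severe_maternal_outcome_rate`,
#'   `flagged`.
#' @export
facility_indicators <- function(ds) {
  stopifnot(inherits(ds, "facility_dataset"))
  r <- ds$records
  if (all(is.na(r$facility_id))) stop("facility_id not populated")
  fac <- unique(r$facility_id)
  rows <- lapply(fac, function(f) {
    s <- r[r$facility_id %in% f, , drop = FALSE]
    lb <- sum(s$livebirth, na.rm = TRUE)
    has_mode <- !is.na(s$mode_of_delivery)
    ipd <- sum(s$intrapartum_stillbirth, na.rm = TRUE) +
      sum(s$neonatal_death_day1, na.rm = TRUE)
    md <- sum(s$maternal_death, na.rm = TRUE)
    nm <- sum(s$maternal_near_miss, na.rm = TRUE)
    per_lb <- function(count, scale) if (lb > 0) scale * count / lb else NA_real_
    data.frame(
      facility_id = f,
      n_women = nrow(s),
      n_livebirths = lb,
      cs_rate = if (any(has_mode))
        100 * sum(s$mode_of_delivery[has_mode] == "caesarean") / sum(has_mode)
        else NA_real_,
      intrapartum_perinatal_mortality = per_lb(ipd, 1000),
      maternal_mortality = per_lb(md, 100000),
      near_miss_rate = per_lb(nm, 1000),
      severe_maternal_outcome_rate = per_lb(nm + md, 1000),
      flagged = lb == 0,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select reference facilities by double-median stratification
#'
#' Computes the 50th percentile of the facility CS rate and of the
#' intrapartum-related perinatal mortality across facilities (median; with an
#' even number of facilities, the midpoint of the two central order
#' statistics) and selects the facilities that lie strictly below BOTH
#' thresholds. Strictness mirrors the "below the 50th percentile" selection
#' rule; when all facilities are identical nothing is strictly below the
#' median and the selection is empty (with a warning).
#'
#' @param indicators Data.frame from [facility_indicators()]; rows with NA in
#'   either indicator are dropped from both the percentile computation and
#'   the selection.
#' @return List with `selected` (facility ids), `cs_rate_threshold`,
#'   `mortality_threshold`, `n_facilities` (with defined indicators).
#' @export
select_reference <- function(indicators) {
  ok <- !is.na(indicators$cs_rate) &
    !is.na(indicators$intrapartum_perinatal_mortality)
  ind <- indicators[ok, , drop = FALSE]
  if (nrow(ind) < 2) stop("need at least 2 facilities with defined indicators")
  thr_cs <- stats::median(ind$cs_rate)
  thr_mort <- stats::median(ind$intrapartum_perinatal_mortality)
  sel <- ind$facility_id[ind$cs_rate < thr_cs &
                         ind$intrapartum_perinatal_mortality < thr_mort]
  if (length(sel) == 0) {
    warning("no facility strictly below both medians; empty reference selection",
            call. = FALSE)
  }
  list(selected = sel, cs_rate_threshold = thr_cs,
       mortality_threshold = thr_mort, n_facilities = nrow(ind))
}

#' Random split of a dataset into model-building and testing subsets
#'
#' Record-level simple random split without replacement: `ceiling(fraction *
#' n)` records to the first subset, the rest to the second. Deterministic
#' given the seed; every record lands in exactly one subset.
#'
#' @param ds A `facility_dataset`.
#' @param fraction Fraction allocated to the first subset (default 0.9).
#' @param seed Integer RNG seed (mandatory, for reproducibility).
#' @return List with `a1` and `a2`, both `facility_dataset`s.
#' @export
split_reference <- function(ds, fraction = 0.9, seed) {
  stopifnot(inherits(ds, "facility_dataset"),
            fraction > 0, fraction < 1, !missing(seed))
  n <- nrow(ds$records)
  n1 <- ceiling(fraction * n)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- sample.int(n, n1)
  a1 <- facility_dataset(ds$records[idx, , drop = FALSE],
                         provenance = paste0(ds$provenance, " [split A1]"))
  a2 <- facility_dataset(ds$records[-idx, , drop = FALSE],
                         provenance = paste0(ds$provenance, " [split A2]"))
  list(a1 = a1, a2 = a2)
}

#' Maximum-likelihood logistic regression from scratch
#'
#' Fits a binary logistic model by iteratively reweighted least squares
#' (Newton-Raphson on the log-likelihood). Convergence is declared when the
#' largest score component falls below `tol_score` (1e-8) or the relative
#' log-likelihood change falls below `tol_ll` (1e-10), within `max_iter`
#' iterations; non-convergence is reported in the result, never silent.
#' Standard errors come from the inverse observed information. A coefficient
#' vector whose Euclidean norm exceeds 50 is taken as evidence of complete
#' separation and raises an error, as does a rank-deficient design.
#'
#' @param X Numeric design matrix (covariates only; an intercept column is
#'   prepended unless `intercept = FALSE`). A zero-column matrix fits the
#'   intercept-only model.
#' @param y 0/1 outcome vector.
#' @param intercept Prepend an intercept column (default TRUE).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol_score,tol_ll Convergence tolerances.
#' @return A `cmodel_fit`: list with `coefficients`, `se`, `loglik`,
#'   `iterations`, `converged`, `n`.
#' @export
fit_logistic <- function(X, y, intercept = TRUE, max_iter = 100L,
                         tol_score = 1e-8, tol_ll = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  .check_binary(y)
  if (intercept) {
    X <- cbind("(Intercept)" = rep(1, length(y)), X)
  }
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n)
  if (n <= p) stop("need more observations than parameters")
  const <- apply(X[, colnames(X) != "(Intercept)", drop = FALSE], 2,
                 function(col) length(unique(col)) == 1L)
  if (any(const)) {
    stop("covariate(s) constant across records: ",
         paste(names(const)[const], collapse = ", "))
  }
  if (qr(X)$rank < p) stop("singular design matrix (rank deficient)")
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  info <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, score),
                     error = function(e) stop("information matrix singular during IRLS"))
    beta <- beta + step
    if (sqrt(sum(beta^2)) > 50) {
      stop("apparent complete separation: coefficient norm exceeds 50")
    }
    eta <- drop(X %*% beta)
    ll <- sum(y * eta - log1p(exp(eta)))
    score <- drop(crossprod(X, y - stats::plogis(eta)))
    if (max(abs(score)) < tol_score ||
        abs(ll - ll_old) < tol_ll * (abs(ll_old) + tol_ll)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  mu <- stats::plogis(drop(X %*% beta))
  info <- crossprod(X, X * (mu * (1 - mu)))
  se <- sqrt(diag(solve(info)))
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    loglik = ll_old, iterations = it, converged = converged, n = n),
    class = "cmodel_fit")
}

#' @export
print.cmodel_fit <- function(x, ...) {
  cat(sprintf("<cmodel_fit> n = %d, logLik = %.2f, %d iteration(s)%s\n",
              x$n, x$loglik, x$iterations,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  est <- data.frame(estimate = x$coefficients, se = x$se)
  print(round(est, 6))
  invisible(x)
}

#' Refit a scoring-model version on a dataset
#'
#' Re-estimates the coefficients of a given version by maximum likelihood on
#' the records of `ds` that are complete under that version and have a
#' recorded mode of delivery. This is a fixed-effects fit: the published
#' model was estimated with facility random intercepts, which we do not
#' reproduce; the relevant acceptance surface here is recovery of fixed
#' coefficient values, and cluster-robust uncertainty can be obtained by a
#' facility-level bootstrap (`cluster_boot` replicates).
#'
#' @param ds A `facility_dataset`.
#' @param version Version id (default `"v1.0"`).
#' @param age_cutoff Passed to [encode_covariates()].
#' @param cluster_boot Number of facility-level bootstrap replicates for
#'   cluster-robust standard errors (0 = none, default).
#' @param seed Seed for the bootstrap (required when `cluster_boot > 0`).
#' @return A `cmodel_fit`; with bootstrap, an extra element `se_cluster`.
#' @export
refit_cmodel <- function(ds, version = "v1.0", age_cutoff = 35,
                         cluster_boot = 0L, seed = NULL) {
  mv <- cmodel_versions(version)
  r <- ds$records
  cov <- encode_covariates(ds, age_cutoff = age_cutoff)
  X <- cov[, mv$covariates, drop = FALSE]
  use <- rowSums(is.na(X)) == 0L & !is.na(r$mode_of_delivery)
  if (sum(use) == 0) stop("no usable records for refitting")
  y <- as.numeric(r$mode_of_delivery[use] == "caesarean")
  fit <- fit_logistic(X[use, , drop = FALSE], y)
  if (cluster_boot > 0L) {
    if (is.null(seed)) stop("seed required for cluster bootstrap")
    fac <- r$facility_id[use]
    ufac <- unique(fac)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    Xu <- X[use, , drop = FALSE]
    boots <- matrix(NA_real_, nrow = cluster_boot,
                    ncol = length(fit$coefficients))
    for (b in seq_len(cluster_boot)) {
      pick <- sample(ufac, length(ufac), replace = TRUE)
      idx <- unlist(lapply(pick, function(f) which(fac == f)))
      bf <- tryCatch(fit_logistic(Xu[idx, , drop = FALSE], y[idx]),
                     error = function(e) NULL)
      if (!is.null(bf)) boots[b, ] <- bf$coefficients
    }
    fit$se_cluster <- apply(boots, 2, stats::sd, na.rm = TRUE)
    names(fit$se_cluster) <- names(fit$coefficients)
  }
  fit
}
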