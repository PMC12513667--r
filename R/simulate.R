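# Synthetic hypertensive-cohort generator.  Draws cohorts from exactly the
# joint law the model assumes: linear-mixed trajectories for systolic and
# diastolic blood pressure with natural-spline time effects and subject
# random effects, and event times whose hazard depends on functionals of
# the latent trajectories through the chosen association structure.

# baseline covariate prevalences of the emulated clinic population
.default_prevalences <- list(
  age_group_65plus    = 0.25,
  sex_male            = 0.4534,
  fbs_cat_ge125       = 0.3223,
  bun_cat_ge24        = 0.5279,
  tg_cat_ge150        = 0.4585,
  tc_cat_ge200        = 0.3731,
  hdl_cat_lt40        = 0.3280,
  ldl_cat_ge100       = 0.6694,
  proteinuria_positive = 0.3137,
  aki_yes             = 0.2672,
  dm_yes              = 0.2991,
  chd_yes             = 0.3015,
  vd_yes              = 0.2672,
  fhhtn_yes           = 0.2402,
  htn_stage2          = 0.6250,   # stage1 is the remainder
  htn_crisis          = 0.2451,
  treatment_two_plus  = 0.6617
)

# fixed effects on the internal mmHg/10 scale
.default_beta <- list(
  sbp = c("(Intercept)" = 11.99, time1 = -0.13, time2 = -1.41, time3 = -0.37,
          sex_male = 0.072, dm_yes = 0.17, chd_yes = 0.12, aki_yes = 0.04,
          htn_stage_stage2 = 0.16, htn_stage_crisis = 0.46,
          treatment_two_plus = -0.02, htn_duration_dec = -0.13),
  dbp = c("(Intercept)" = 9.19, time1 = -0.14, time2 = -0.95, time3 = -0.37,
          sex_male = 0.09, dm_yes = 0.45, chd_yes = 0.38, aki_yes = 0.07,
          htn_stage_stage2 = 0.15, htn_stage_crisis = 0.50,
          treatment_two_plus = -0.04, htn_duration_dec = -0.08)
)

# log hazard ratios of the baseline covariates in the event submodel
.default_gamma <- c(
  age_group_65plus = log(4.64), sex_male = log(0.43),
  tg_cat_ge150 = log(1.33), tc_cat_ge200 = log(1.06),
  hdl_cat_lt40 = log(3.32), bun_cat_ge24 = log(1.69),
  dm_yes = log(3.08), chd_yes = log(1.89), vd_yes = log(1.16),
  proteinuria_positive = log(2.85), aki_yes = log(1.83),
  treatment_two_plus = log(0.78))

# association coefficients (log hazard ratios per internal unit / per
# quarterly rate of change)
.default_alpha <- c(sbp_value = log(6.25), sbp_slope = log(3.75),
                    dbp_value = log(4.32), dbp_slope = log(5.64))

#' Configuration of the synthetic-cohort generator
#'
#' Returns a validated generator configuration whose defaults emulate the
#' study conditions: 408 subjects, quarterly visits up to 120 months,
#' baseline covariate prevalences matching the clinic population,
#' trajectory fixed effects, random-effect standard deviations and residual
#' noise on the internal mmHg/10 scale, event hazard driven by the current
#' value and quarterly slope of both trajectories, exponential loss to
#' follow-up plus administrative censoring at 120 months (tuned to a
#' cumulative event fraction near 14%), and sparse missingness of scheduled
#' blood-pressure values.
#'
#' @param n_subjects number of subjects.
#' @param visit_interval_m scheduled visit spacing in months.
#' @param max_followup_m administrative censoring horizon in months.
#' @param covariate_prevalences named list of Bernoulli prevalences for the
#'   binary baseline covariates (plus `htn_stage2`/`htn_crisis`).
#' @param basis [time_basis()] for the trajectory time effects.
#' @param beta named list (`sbp`, `dbp`) of fixed-effect vectors on the
#'   internal scale; names must match the model-matrix columns.
#' @param re_sd named list of random-effect standard deviations per outcome
#'   (intercept followed by the basis columns).
#' @param re_cross optional correlation between the two outcomes' random
#'   intercepts (default 0 gives the block-diagonal covariance).
#' @param sigma_eps named residual standard deviations (internal scale).
#' @param baseline_hazard list with `cutpoints` (interior boundaries,
#'   months) and `heights` (per-interval hazards per month).
#' @param gamma named log hazard ratios of the baseline covariates.
#' @param alpha named association coefficients; names are
#'   `<outcome>_<term>` for the active terms of `association`.
#' @param association one of `"current_value"`, `"slope"`,
#'   `"value_and_slope"`, `"area"`, `"area_and_value"`.
#' @param centers named per-outcome centering constants for the value/area
#'   association terms (internal scale).
#' @param censoring_rate exponential loss-to-follow-up rate per month.
#' @param missing_rate probability that a scheduled pressure value is
#'   missing.
#' @param seed integer seed; all randomness flows from it through named
#'   substreams so stages are independently reproducible.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 408,
                             visit_interval_m = 3,
                             max_followup_m = 120,
                             covariate_prevalences = .default_prevalences,
                             basis = time_basis(c(0, 120), c(40, 80)),
                             beta = .default_beta,
                             re_sd = list(sbp = c(0.36, 0.54, 0.89, 0.53),
                                          dbp = c(0.497, 0.37, 0.77, 0.45)),
                             re_cross = 0,
                             sigma_eps = c(sbp = 0.62, dbp = 0.53),
                             baseline_hazard = list(cutpoints = numeric(0),
                                                    heights = 8e-6),
                             gamma = .default_gamma,
                             alpha = .default_alpha,
                             association = "value_and_slope",
                             centers = c(sbp = 11.2, dbp = 8.7),
                             censoring_rate = 0.0075,
                             missing_rate = 0.002,
                             seed = 1) {
  association <- match.arg(association, .assoc_structures)
  stopifnot(n_subjects >= 0, visit_interval_m > 0, max_followup_m > 0,
            all(unlist(covariate_prevalences) >= 0),
            all(unlist(covariate_prevalences) <= 1),
            all(sigma_eps >= 0), censoring_rate >= 0,
            missing_rate >= 0, missing_rate <= 1)
  .bh_validate(baseline_hazard)
  q <- basis$df + 1L
  for (k in c("sbp", "dbp"))
    stopifnot(length(re_sd[[k]]) == q)
  stopifnot(abs(re_cross) < 1)
  want <- .alpha_names(association)
  if (!all(want %in% names(alpha)))
    stop("alpha must contain coefficients named: ", paste(want, collapse = ", "))
  alpha <- alpha[want]
  cfg <- list(n_subjects = as.integer(n_subjects),
              visit_interval_m = visit_interval_m,
              max_followup_m = max_followup_m,
              covariate_prevalences = covariate_prevalences,
              basis = basis, beta = beta, re_sd = re_sd, re_cross = re_cross,
              sigma_eps = sigma_eps, baseline_hazard = baseline_hazard,
              gamma = gamma, alpha = alpha, association = association,
              centers = centers, censoring_rate = censoring_rate,
              missing_rate = missing_rate, seed = as.integer(seed))
  # random-effects covariance: block per outcome (diagonal within block),
  # optional intercept cross-correlation between outcomes
  D <- diag(c(re_sd$sbp, re_sd$dbp)^2)
  if (re_cross != 0) {
    i <- 1; j <- q + 1
    D[i, j] <- D[j, i] <- re_cross * re_sd$sbp[1] * re_sd$dbp[1]
  }
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("random-effects covariance is not positive definite")
  cfg$D <- D
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("synthetic cohort generator:", x$n_subjects, "subjects,",
      x$association, "association\n")
  cat(sprintf("  visits every %g months up to %g; censoring %g/month; missing %g\n",
              x$visit_interval_m, x$max_followup_m, x$censoring_rate,
              x$missing_rate))
  invisible(x)
}

#' Scheduled visit times
#'
#' Grid of scheduled measurement times `0, interval, 2*interval, ...`
#' strictly below the follow-up time.
#'
#' @param followup_m follow-up in months (> 0).
#' @param interval_m spacing in months (> 0).
#' @return numeric vector of visit times.
#' @export
schedule_visits <- function(followup_m, interval_m = 3) {
  if (interval_m <= 0) stop("visit interval must be positive")
  stopifnot(followup_m > 0)
  tt <- seq(0, followup_m, by = interval_m)
  tt[tt < followup_m]
}

# deterministic per-stage substream seed
.substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000000000L) * 2L + (h %% 1000L)
}

# simulate the baseline covariate table
.simulate_baseline <- function(n, prev, seed) {
  set.seed(.substream(seed, "covariates"))
  rb <- function(p) stats::rbinom(n, 1, p)
  lv <- .baseline_levels
  pick <- function(var, ind) lv[[var]][ind + 1]
  stage_u <- stats::runif(n)
  stage <- ifelse(stage_u < prev$htn_crisis, "crisis",
                  ifelse(stage_u < prev$htn_crisis + prev$htn_stage2,
                         "stage2", "stage1"))
  data.frame(
    subject_id  = sprintf("S%04d", seq_len(n)),
    age_group   = pick("age_group", rb(prev$age_group_65plus)),
    sex         = pick("sex", rb(prev$sex_male)),
    fbs_cat     = pick("fbs_cat", rb(prev$fbs_cat_ge125)),
    bun_cat     = pick("bun_cat", rb(prev$bun_cat_ge24)),
    tg_cat      = pick("tg_cat", rb(prev$tg_cat_ge150)),
    tc_cat      = pick("tc_cat", rb(prev$tc_cat_ge200)),
    hdl_cat     = pick("hdl_cat", rb(prev$hdl_cat_lt40)),
    ldl_cat     = pick("ldl_cat", rb(prev$ldl_cat_ge100)),
    proteinuria = pick("proteinuria", rb(prev$proteinuria_positive)),
    aki         = pick("aki", rb(prev$aki_yes)),
    dm          = pick("dm", rb(prev$dm_yes)),
    chd         = pick("chd", rb(prev$chd_yes)),
    vd          = pick("vd", rb(prev$vd_yes)),
    fhhtn       = pick("fhhtn", rb(prev$fhhtn_yes)),
    htn_stage   = stage,
    treatment   = pick("treatment", rb(prev$treatment_two_plus)),
    htn_duration = round(stats::rgamma(n, shape = 2, scale = 2), 2),
    stringsAsFactors = FALSE)
}

#' Dummy-coded covariate matrix for a set of baseline variables
#'
#' One column per non-reference level, named `<var>_<level>`; the numeric
#' hypertension duration enters as decades (`htn_duration_dec`).
#'
#' @param baseline baseline covariate data.frame.
#' @param vars character vector of variable names.
#' @return numeric matrix with one row per subject.
#' @export
covariate_dummies <- function(baseline, vars) {
  cols <- list()
  for (v in vars) {
    if (v == "htn_duration") {
      cols[["htn_duration_dec"]] <- baseline$htn_duration / 10
    } else {
      lev <- .baseline_levels[[v]]
      if (is.null(lev)) stop("unknown baseline covariate: ", v)
      bad <- !(baseline[[v]] %in% lev)
      if (any(bad)) stop("unseen level in '", v, "': ",
                         paste(unique(baseline[[v]][bad]), collapse = ", "))
      for (l in lev[-1])
        cols[[paste(v, l, sep = "_")]] <- as.numeric(baseline[[v]] == l)
    }
  }
  m <- do.call(cbind, cols)
  if (is.null(m)) m <- matrix(0, nrow(baseline), 0)
  rownames(m) <- baseline$subject_id
  m
}

# variables referenced by a named coefficient vector
.vars_from_names <- function(nms) {
  nms <- setdiff(nms, c("(Intercept)", paste0("time", 1:9)))
  vars <- character(0)
  for (v in c(names(.baseline_levels), "htn_duration")) {
    pref <- if (v == "htn_duration") "htn_duration_dec" else paste0(v, "_")
    if (any(startsWith(nms, pref))) vars <- c(vars, v)
  }
  vars
}

#' Simulate a cohort with known truth
#'
#' Draws baseline covariates, subject random effects, latent trajectories,
#' event and censoring times, scheduled visits with measurement noise and
#' missingness -- the exact data-generating process assumed by the joint
#' model.  Event times are obtained by inverting each subject's cumulative
#' hazard with [simulate_event_time()].
#'
#' @param config a [generator_config()].
#' @return list with elements `cohort` (a [cohort()]) and `truth`
#'   (class `cohort_truth`: random effects, true event and censoring times,
#'   and the configuration).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_subjects
  if (n == 0) {
    empty <- cohort(
      data.frame(subject_id = character(0), time_m = numeric(0),
                 sbp = numeric(0), dbp = numeric(0)),
      data.frame(subject_id = character(0)),
      data.frame(subject_id = character(0), followup_m = numeric(0),
                 event = integer(0)))
    return(list(cohort = empty,
                truth = structure(list(b = NULL, event_time = numeric(0),
                                       censor_time = numeric(0),
                                       config = config),
                                  class = "cohort_truth")))
  }
  basis <- config$basis
  q <- basis$df + 1L

  baseline <- .simulate_baseline(n, config$covariate_prevalences, config$seed)

  set.seed(.substream(config$seed, "effects"))
  b <- .rmvnorm_chol(n, config$D)          # n x 2q, sbp block then dbp block
  colnames(b) <- c(paste0("sbp_b", 0:(q - 1)), paste0("dbp_b", 0:(q - 1)))

  # per-subject trajectory parameters (intercept part a, basis part theta)
  eta_pars_all <- vector("list", n)
  Wg <- covariate_dummies(baseline, .vars_from_names(names(config$gamma)))
  gname <- intersect(names(config$gamma), colnames(Wg))
  lin_w <- if (length(gname)) drop(Wg[, gname, drop = FALSE] %*%
                                     config$gamma[gname]) else rep(0, n)
  for (i in seq_len(n)) {
    pars <- list()
    for (ki in 1:2) {
      k <- c("sbp", "dbp")[ki]
      be <- config$beta[[k]]
      Wl <- covariate_dummies(baseline[i, , drop = FALSE],
                              .vars_from_names(names(be)))
      cov_eff <- sum(be[intersect(names(be), colnames(Wl))] *
                       Wl[1, intersect(names(be), colnames(Wl))])
      bi <- b[i, ((ki - 1) * q + 1):(ki * q)]
      pars[[k]] <- list(a = unname(be["(Intercept)"]) + cov_eff + bi[1],
                        theta = be[paste0("time", seq_len(basis$df))] +
                          bi[-1])
    }
    eta_pars_all[[i]] <- pars
  }

  set.seed(.substream(config$seed, "event"))
  u <- stats::runif(n)
  event_time <- vapply(seq_len(n), function(i)
    simulate_event_time(u[i], config$baseline_hazard, lin_w[i],
                        config$alpha, config$association, eta_pars_all[[i]],
                        config$centers, basis,
                        horizon = config$max_followup_m), numeric(1))

  set.seed(.substream(config$seed, "censoring"))
  censor_time <- if (config$censoring_rate > 0)
    pmin(stats::rexp(n, config$censoring_rate), config$max_followup_m)
  else rep(config$max_followup_m, n)

  followup <- pmin(event_time, censor_time)
  event <- as.integer(event_time <= censor_time & is.finite(event_time))
  # guarantee a strictly positive follow-up (events inside the first day
  # are recorded at a minimal resolution)
  followup <- pmax(followup, 0.03)

  set.seed(.substream(config$seed, "noise"))
  vis <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- schedule_visits(followup[i], config$visit_interval_m)
    pars <- eta_pars_all[[i]]
    mu_s <- eta_eval(tt, pars$sbp$a, pars$sbp$theta, basis)
    mu_d <- eta_eval(tt, pars$dbp$a, pars$dbp$theta, basis)
    sbp <- 10 * (mu_s + stats::rnorm(length(tt), 0, config$sigma_eps["sbp"]))
    dbp <- 10 * (mu_d + stats::rnorm(length(tt), 0, config$sigma_eps["dbp"]))
    # enforce the physiological ordering; redraw the rare crossing pair
    bad <- which(sbp <= dbp)
    guard <- 0
    while (length(bad) && guard < 100) {
      sbp[bad] <- 10 * (mu_s[bad] + stats::rnorm(length(bad), 0,
                                                 config$sigma_eps["sbp"]))
      dbp[bad] <- 10 * (mu_d[bad] + stats::rnorm(length(bad), 0,
                                                 config$sigma_eps["dbp"]))
      bad <- which(sbp <= dbp)
      guard <- guard + 1
    }
    if (length(bad)) dbp[bad] <- sbp[bad] - 1  # degenerate noise settings
    vis[[i]] <- data.frame(subject_id = baseline$subject_id[i], time_m = tt,
                           sbp = sbp, dbp = dbp, stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, vis)

  if (config$missing_rate > 0) {
    set.seed(.substream(config$seed, "missingness"))
    visits$sbp[stats::runif(nrow(visits)) < config$missing_rate] <- NA
    visits$dbp[stats::runif(nrow(visits)) < config$missing_rate] <- NA
  }

  outcomes <- data.frame(subject_id = baseline$subject_id,
                         followup_m = followup, event = event,
                         stringsAsFactors = FALSE)
  rownames(b) <- baseline$subject_id
  truth <- structure(list(b = b, event_time = event_time,
                          censor_time = censor_time,
                          eta_pars = eta_pars_all, lin_pred_w = lin_w,
                          config = config),
                     class = "cohort_truth")
  list(cohort = cohort(visits, baseline, outcomes), truth = truth)
}

#' @export
print.cohort_truth <- function(x, ...) {
  n <- length(x$event_time)
  cat("generator truth for", n, "subjects;",
      sum(is.finite(x$event_time)), "latent events within horizon\n")
  invisible(x)
}
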