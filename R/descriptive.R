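# Person-time incidence, Kaplan-Meier estimation, log-rank comparison, Cox
# proportional-hazards screening and residual diagnostics.  Estimation is
# delegated to the survival package; this module shapes the study's inputs
# and outputs around it.

#' @importFrom survival Surv survfit survdiff coxph cox.zph coxph.control
NULL

#' Person-time and incidence density
#'
#' Total person-years are the summed follow-up months divided by 12; the
#' incidence density is reported per 100 person-years with an exact Poisson
#' 95% confidence interval from chi-square quantiles.  Also reports the
#' cumulative incidence proportion with a Clopper-Pearson interval.
#'
#' @param outcomes outcome table (`followup_m`, `event`) or a [cohort()].
#' @param n_events,person_years alternatively, enter the two totals
#'   directly (both must be given; `outcomes` is then ignored).
#' @param conf level for the intervals.
#' @return object of class `incidence_result`.
#' @export
incidence_density <- function(outcomes = NULL, n_events = NULL,
                              person_years = NULL, conf = 0.95) {
  if (is.null(n_events) != is.null(person_years))
    stop("give both n_events and person_years, or neither")
  n_subjects <- NA_integer_
  if (is.null(n_events)) {
    if (inherits(outcomes, "cohort")) outcomes <- outcomes$outcomes
    if (!nrow(outcomes)) stop("empty outcome table")
    n_events <- sum(outcomes$event)
    person_years <- sum(outcomes$followup_m) / 12
    n_subjects <- nrow(outcomes)
  }
  if (person_years <= 0) stop("zero total person-time")
  a <- 1 - conf
  rate <- 100 * n_events / person_years
  lo <- if (n_events == 0) 0 else
    100 * stats::qchisq(a / 2, 2 * n_events) / 2 / person_years
  hi <- 100 * stats::qchisq(1 - a / 2, 2 * (n_events + 1)) / 2 / person_years
  prop <- prop_ci <- NULL
  if (!is.na(n_subjects)) {
    bt <- stats::binom.test(n_events, n_subjects, conf.level = conf)
    prop <- 100 * n_events / n_subjects
    prop_ci <- 100 * as.numeric(bt$conf.int)
  }
  structure(list(n_events = n_events, person_years = person_years,
                 rate_per_100py = rate, ci95 = c(lo, hi),
                 n_subjects = n_subjects, proportion_pct = prop,
                 proportion_ci95 = prop_ci, conf = conf),
            class = "incidence_result")
}

#' @export
print.incidence_result <- function(x, ...) {
  cat(sprintf("%d events over %.2f person-years\n", x$n_events,
              x$person_years))
  cat(sprintf("incidence density: %.2f per 100 PY (%.0f%% CI %.2f-%.2f)\n",
              x$rate_per_100py, 100 * x$conf, x$ci95[1], x$ci95[2]))
  if (!is.na(x$n_subjects))
    cat(sprintf("cumulative incidence: %.2f%% (%.2f-%.2f)\n",
                x$proportion_pct, x$proportion_ci95[1], x$proportion_ci95[2]))
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with Greenwood variance and a log-transformed
#' 95% confidence band.
#'
#' @param outcomes outcome table or [cohort()].
#' @return object of class `km_curve` with the step-function values at the
#'   distinct event times (time 0 included).
#' @export
km_estimate <- function(outcomes) {
  if (inherits(outcomes, "cohort")) outcomes <- outcomes$outcomes
  if (!nrow(outcomes)) stop("at least one subject required")
  if (any(outcomes$followup_m < 0)) stop("negative follow-up time")
  sf <- survfit(Surv(followup_m, event) ~ 1, data = outcomes,
                conf.type = "log")
  structure(list(time = c(0, sf$time), survival = c(1, sf$surv),
                 greenwood_var = c(0, sf$std.err^2 * sf$surv^2),
                 lower = c(1, sf$lower), upper = c(1, sf$upper),
                 n = nrow(outcomes)),
            class = "km_curve")
}

#' @rdname km_estimate
#' @param curve a `km_curve`.
#' @param t time(s) in months.
#' @return `km_at`: the step-function survival value at `t`.
#' @export
km_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- findInterval(t, curve$time)
  curve$survival[pmax(idx, 1)]
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve on", x$n, "subjects;", length(x$time) - 1,
      "distinct times\n")
  for (m in c(24, 48, 72, 96))
    if (m <= max(x$time))
      cat(sprintf("  S(%d months) = %.3f\n", m, km_at(x, m)))
  invisible(x)
}

#' Export a Kaplan-Meier curve as a data frame
#' @param x a `km_curve`.
#' @param ... unused.
#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, survival = x$survival,
             lower = x$lower, upper = x$upper)
}

#' Log-rank test across groups
#'
#' @param outcomes outcome table or [cohort()].
#' @param group one label per subject.
#' @return list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(outcomes, group) {
  if (inherits(outcomes, "cohort")) outcomes <- outcomes$outcomes
  group <- factor(group)
  if (nlevels(group) < 2) stop("log-rank test requires at least two groups")
  sd <- survdiff(Surv(outcomes$followup_m, outcomes$event) ~ group)
  df <- length(sd$n) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Fits the event submodel's frequentist screen
#' \eqn{h_i(t) = h_0(t)\exp(w_i'\gamma)} by partial likelihood with Efron
#' (default) or Breslow tie handling, and attaches the residual
#' diagnostics: per-subject martingale residuals (which sum to zero at the
#' optimum) and the scaled-Schoenfeld proportional-hazards test.
#'
#' @param outcomes outcome table or [cohort()].
#' @param covariates numeric matrix/data.frame, one row per subject in the
#'   order of `outcomes`.
#' @param ties `"efron"` or `"breslow"`.
#' @return object of class `cox_fit`.
#' @export
cox_fit <- function(outcomes, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (inherits(outcomes, "cohort")) outcomes <- outcomes$outcomes
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!sum(outcomes$event)) stop("no events; cannot fit")
  const <- apply(X, 2, function(v) length(unique(v)) == 1)
  if (any(const)) stop("constant covariate(s): ",
                       paste(colnames(X)[const], collapse = ", "))
  dat <- data.frame(.time = outcomes$followup_m, .event = outcomes$event, X,
                    check.names = FALSE)
  fml <- stats::as.formula(paste(
    "Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- withCallingHandlers(
    coxph(fml, data = dat, ties = ties,
          control = coxph.control(eps = 1e-11, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w)))
        stop("monotone likelihood or non-convergence in Cox fit: ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  structure(list(coef = stats::coef(fit), se = sqrt(diag(stats::vcov(fit))),
                 hr = exp(stats::coef(fit)), loglik = fit$loglik[2],
                 martingale = unname(stats::residuals(fit, type = "martingale")),
                 model = fit, ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties)\n", sep = "")
  tab <- data.frame(coef = x$coef, se = x$se, hr = x$hr,
                    lower = exp(x$coef - 1.96 * x$se),
                    upper = exp(x$coef + 1.96 * x$se))
  print(round(tab, 4))
  invisible(x)
}

#' Proportional-hazards and goodness-of-fit diagnostics
#'
#' Scaled Schoenfeld residuals are tested for a trend in event-time rank
#' (per covariate and globally); martingale residuals are returned for
#' functional-form assessment.
#'
#' @param fit a [cox_fit()].
#' @return list with `schoenfeld` (data.frame: covariate, chi-square, df,
#'   p; last row GLOBAL) and `martingale`.
#' @export
ph_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!sum(fit$model$nevent)) stop("no events; diagnostics undefined")
  zp <- cox.zph(fit$model, transform = "rank")
  tab <- as.data.frame(zp$table)
  names(tab) <- c("chi2", "df", "p")
  tab$covariate <- rownames(tab)
  rownames(tab) <- NULL
  list(schoenfeld = tab[c("covariate", "chi2", "df", "p")],
       martingale = fit$martingale)
}

#' Bivariable Cox screen
#'
#' Fits one Cox model per covariate and reports which pass the inclusion
#' threshold used when assembling the multivariable event submodel
#' (p <= 0.25 by default).  A reporting helper; the joint model's covariate
#' list remains user-specified.
#'
#' @param outcomes outcome table or [cohort()].
#' @param covariates numeric matrix, one column per candidate.
#' @param p_threshold inclusion threshold.
#' @return data.frame: covariate, coef, hr, p, include.
#' @export
bivariable_screen <- function(outcomes, covariates, p_threshold = 0.25) {
  if (inherits(outcomes, "cohort")) outcomes <- outcomes$outcomes
  X <- as.matrix(covariates)
  rows <- lapply(colnames(X), function(nm) {
    f <- cox_fit(outcomes, X[, nm, drop = FALSE])
    z <- f$coef / f$se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(covariate = nm, coef = unname(f$coef), hr = unname(f$hr),
               p = unname(p), include = unname(p <= p_threshold))
  })
  do.call(rbind, rows)
}
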