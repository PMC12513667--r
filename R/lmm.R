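# Linear mixed-effects submodels for the blood-pressure trajectories:
# design construction with natural-spline time effects, maximum-likelihood
# fitting (lme4), and AIC/BIC selection of the random-effects structure.
# Outcomes are modelled on the internal mmHg/10 scale throughout.

#' Build the longitudinal design for one outcome
#'
#' Rows are the non-missing measurements of the chosen outcome.  The fixed
#' design is `[1, spline basis(t), covariate dummies]`; the random design
#' is `[1, spline basis(t)]` per subject.  Reference levels are female, no
#' comorbidity, stage-1 hypertension, single drug regimen.
#'
#' @param x a [cohort()].
#' @param outcome `"sbp"` or `"dbp"`.
#' @param basis a [time_basis()]; by default boundary knots at 0 and the
#'   maximum observed visit time, interior knots at the 33rd/67th
#'   percentiles of observed visit times.
#' @param covariates baseline variables for the fixed design (may be
#'   empty).
#' @return list of class `lmm_design` with `X`, `Z`, `y` (internal scale),
#'   `grouping`, `time`, `basis`, `covariates`, `outcome`.
#' @export
build_design <- function(x, outcome = c("sbp", "dbp"), basis = NULL,
                         covariates = character(0)) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(x, "cohort"))
  v <- x$visits[!is.na(x$visits[[outcome]]), , drop = FALSE]
  if (!nrow(v)) stop("no observed ", outcome, " values")
  if (is.null(basis)) {
    qs <- unname(stats::quantile(v$time_m, c(1, 2) / 3, type = 7))
    qs <- qs[qs > 0 & qs < max(v$time_m)]
    basis <- time_basis(c(0, max(max(v$time_m), 1)), unique(qs))
  }
  B <- basis_eval(basis, v$time_m)
  W <- covariate_dummies(x$baseline, covariates)
  Wrow <- W[match(v$subject_id, x$baseline$subject_id), , drop = FALSE]
  X <- cbind("(Intercept)" = 1, B, Wrow)
  Z <- cbind("(Intercept)" = 1, B)
  structure(list(X = X, Z = Z, y = v[[outcome]] / 10,
                 grouping = v$subject_id, time = v$time_m, basis = basis,
                 covariates = covariates, outcome = outcome),
            class = "lmm_design")
}

# random-design columns used by each structure
.random_cols <- function(design, random) {
  switch(random,
         intercept = 1L,
         intercept_slope = 1:2,
         full = seq_len(ncol(design$Z)),
         stop("unknown random structure: ", random))
}

#' Fit a linear mixed model by maximum likelihood
#'
#' Maximizes the marginal Gaussian likelihood (ML, not REML, so that
#' AIC/BIC comparisons across fixed-effect sets are coherent).  The random
#' structure is `"intercept"`, `"intercept_slope"` (intercept plus the
#' first basis column), or `"full"` (intercept plus all basis columns).
#'
#' @param design an [build_design()] result.
#' @param random random-effects structure.
#' @return object of class `lmm_fit`: `beta`, `D_hat`, `sigma2_hat`,
#'   `loglik`, `aic`, `bic`, `blups` (matrix, one row per subject),
#'   `singular` flag, plus the design metadata.
#' @export
fit_lmm <- function(design, random = c("full", "intercept",
                                       "intercept_slope")) {
  random <- match.arg(random)
  stopifnot(inherits(design, "lmm_design"))
  zc <- .random_cols(design, random)
  dat <- as.data.frame(design$X[, -1, drop = FALSE])
  fix_terms <- names(dat)
  dat$.y <- design$y
  dat$.id <- design$grouping
  re_terms <- c("1", sprintf("`%s`",
                             setdiff(colnames(design$Z)[zc], "(Intercept)")))
  fml <- stats::as.formula(paste(
    ".y ~", if (length(fix_terms)) paste(sprintf("`%s`", fix_terms),
                                         collapse = " + ") else "1",
    "+ (", paste(re_terms, collapse = " + "), "| .id)"))
  fit <- lme4::lmer(fml, data = dat, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular =
                                                  lme4::.makeCC("ignore", tol = 1e-4)))
  vc <- lme4::VarCorr(fit)
  D <- vc$.id
  attr(D, "stddev") <- attr(D, "correlation") <- NULL
  D <- as.matrix(D)
  sigma2 <- stats::sigma(fit)^2
  ll <- as.numeric(stats::logLik(fit))
  p <- length(lme4::fixef(fit)) + length(zc) * (length(zc) + 1) / 2 + 1
  N <- length(design$y)
  re <- as.matrix(lme4::ranef(fit)$.id)
  beta <- lme4::fixef(fit)
  names(beta) <- gsub("`", "", names(beta))
  structure(list(beta = beta, D_hat = D, sigma2_hat = sigma2, loglik = ll,
                 aic = -2 * ll + 2 * p, bic = -2 * ll + p * log(N),
                 n_par = p, n_obs = N, blups = re,
                 singular = lme4::isSingular(fit, tol = 1e-5),
                 random = random, basis = design$basis,
                 covariates = design$covariates, outcome = design$outcome,
                 y_digest = sum(design$y) + N),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("linear mixed model for %s (random: %s)%s\n", x$outcome,
              x$random, if (x$singular) " [singular fit]" else ""))
  cat(sprintf("  logLik %.2f  AIC %.2f  BIC %.2f  sigma %.3f\n",
              x$loglik, x$aic, x$bic, sqrt(x$sigma2_hat)))
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  cat("  random-effect SDs:", paste(round(sqrt(diag(x$D_hat)), 3),
                                    collapse = ", "), "\n")
  invisible(x)
}

# fixed/random design rows for one subject at arbitrary times, matching
# the column order used by fit_lmm (needed by predictive imputation)
.lmm_subject_design <- function(fit, x, id, t) {
  B <- basis_eval(fit$basis, t)
  brow <- x$baseline[x$baseline$subject_id == id, , drop = FALSE]
  W <- covariate_dummies(brow, fit$covariates)
  X <- cbind(1, B, W[rep(1, length(t)), , drop = FALSE])
  colnames(X) <- names(fit$beta)
  zc <- .random_cols(list(Z = cbind(1, B)), fit$random)
  list(X = X, Z = cbind(1, B)[, zc, drop = FALSE])
}

#' Select the random-effects structure by information criteria
#'
#' Returns the structure minimizing AIC; when AIC and BIC disagree the
#' AIC choice is returned with a `disagreement` flag.  Ties break toward
#' fewer parameters.
#'
#' @param fits named list of [fit_lmm()] results on identical data.
#' @return list with `chosen`, `table` (structure, n_par, aic, bic),
#'   `disagreement`.
#' @export
select_random_structure <- function(fits) {
  stopifnot(length(fits) >= 2)
  dg <- vapply(fits, function(f) f$y_digest, numeric(1))
  if (max(abs(dg - dg[1])) > 1e-8)
    stop("fits were not estimated on identical data")
  tab <- data.frame(
    structure = if (!is.null(names(fits))) names(fits)
                else vapply(fits, `[[`, "", "random"),
    n_par = vapply(fits, `[[`, numeric(1), "n_par"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic"))
  pick <- function(crit) {
    o <- order(tab[[crit]], tab$n_par)
    tab$structure[o[1]]
  }
  a <- pick("aic"); b <- pick("bic")
  list(chosen = a, table = tab[order(tab$aic), ], disagreement = !identical(a, b))
}
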