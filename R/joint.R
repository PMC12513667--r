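# Bayesian multivariate joint model: latent blood-pressure trajectories
# (linear mixed submodels) linked to the CKD hazard through value / slope /
# area functionals, fitted by Metropolis-within-Gibbs MCMC.  Residual
# variances, random-effects covariances and baseline-hazard heights have
# conjugate full conditionals; fixed effects, survival coefficients,
# association coefficients and subject random effects are updated by
# adaptive random-walk Metropolis.

#' Prior specification for the joint model
#'
#' Vague normal priors for the fixed effects, survival coefficients and
#' association coefficients; inverse-gamma for the residual variances;
#' independent gamma for the baseline-hazard heights; inverse-Wishart
#' (df q+1, identity scale) for the random-effects covariance blocks.
#'
#' The headline normal prior is "mean 0, 0.001" -- interpreted as a
#' *precision* of 0.001 (variance 1000), the vague reading consistent with
#' a noninformative analysis; set `normal_0.001_is = "variance"` for the
#' literal strongly-informative reading.
#'
#' @param beta_precision,gamma_precision,alpha_precision normal prior
#'   precisions.
#' @param sigma2_shape,sigma2_scale inverse-gamma hyperparameters for the
#'   residual variances.
#' @param lambda_shape,lambda_rate gamma hyperparameters for the
#'   baseline-hazard heights.
#' @param normal_0.001_is `"precision"` (default) or `"variance"`.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(beta_precision = 0.001, gamma_precision = 0.001,
                       alpha_precision = 0.001, sigma2_shape = 1,
                       sigma2_scale = 0.005, lambda_shape = 0.01,
                       lambda_rate = 0.01,
                       normal_0.001_is = c("precision", "variance")) {
  normal_0.001_is <- match.arg(normal_0.001_is)
  if (normal_0.001_is == "variance") {
    beta_precision <- 1 / beta_precision
    gamma_precision <- 1 / gamma_precision
    alpha_precision <- 1 / alpha_precision
  }
  stopifnot(beta_precision > 0, gamma_precision > 0, alpha_precision > 0,
            sigma2_shape > 0, sigma2_scale > 0, lambda_shape > 0,
            lambda_rate > 0)
  structure(list(beta_precision = beta_precision,
                 gamma_precision = gamma_precision,
                 alpha_precision = alpha_precision,
                 sigma2_shape = sigma2_shape, sigma2_scale = sigma2_scale,
                 lambda_shape = lambda_shape, lambda_rate = lambda_rate),
            class = "prior_spec")
}

#' MCMC settings
#'
#' Defaults follow the full analysis protocol: 3 chains of 100,000
#' iterations, 25,000 burn-in, thinning 12, 15 Gauss-Legendre nodes per
#' baseline interval, proposal adaptation during burn-in only.  Tests and
#' examples use much smaller runs.
#'
#' @param chains,total_iterations,burn_in,thin,seed,quadrature_points,adapt
#'   see Description.
#' @return object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 3, total_iterations = 100000,
                          burn_in = 25000, thin = 12, seed = 1,
                          quadrature_points = 15, adapt = TRUE) {
  stopifnot(chains >= 1, burn_in <= total_iterations, thin >= 1,
            quadrature_points >= 2)
  structure(list(chains = as.integer(chains),
                 total_iterations = as.integer(total_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 quadrature_points = as.integer(quadrature_points),
                 adapt = isTRUE(adapt)),
            class = "mcmc_settings")
}

#' Joint model specification
#'
#' @param association one of `"current_value"`, `"slope"`,
#'   `"value_and_slope"`, `"area"`, `"area_and_value"`.
#' @param outcomes longitudinal outcomes to include (`"sbp"`, `"dbp"`).
#' @param long_covariates baseline covariates of the trajectory fixed
#'   design (shared by the outcomes).
#' @param surv_covariates baseline covariates of the event submodel.
#' @param basis optional [time_basis()]; defaults to boundary knots at 0
#'   and the maximum observed visit time with interior knots at the
#'   33rd/67th visit-time percentiles.
#' @param n_intervals piecewise-constant baseline-hazard intervals (knots
#'   at event-time quantiles).
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_settings()].
#' @param centers optional named per-outcome centering constants for the
#'   value/area association terms (internal scale); default: the mean
#'   observed value of each outcome.
#' @return object of class `joint_model_spec`.
#' @export
joint_model_spec <- function(association = "value_and_slope",
                             outcomes = c("sbp", "dbp"),
                             long_covariates = character(0),
                             surv_covariates = character(0),
                             basis = NULL, n_intervals = 12,
                             priors = prior_spec(),
                             mcmc = mcmc_settings(), centers = NULL) {
  association <- match.arg(association, .assoc_structures)
  outcomes <- match.arg(outcomes, c("sbp", "dbp"), several.ok = TRUE)
  stopifnot(n_intervals >= 1, inherits(priors, "prior_spec"),
            inherits(mcmc, "mcmc_settings"))
  structure(list(association = association, outcomes = outcomes,
                 long_covariates = long_covariates,
                 surv_covariates = surv_covariates, basis = basis,
                 n_intervals = as.integer(n_intervals), priors = priors,
                 mcmc = mcmc, centers = centers),
            class = "joint_model_spec")
}

# ---------------------------------------------------------------------------
# design: all precomputed arrays the likelihood needs

#' Build the joint-model design arrays for a cohort
#'
#' Precomputes the longitudinal design matrices, the piecewise-constant
#' baseline layout (knots at event-time quantiles), the Gauss-Legendre
#' quadrature grid over each subject's follow-up, and the value / slope /
#' area term designs at the quadrature nodes and at the event times.
#'
#' @param x a [cohort()].
#' @param spec a [joint_model_spec()].
#' @return object of class `jm_design`.
#' @export
jm_design <- function(x, spec) {
  stopifnot(inherits(x, "cohort"), inherits(spec, "joint_model_spec"))
  ids <- x$outcomes$subject_id
  n <- length(ids)
  if (!n) stop("empty cohort")
  basis <- spec$basis
  if (is.null(basis)) {
    tt <- x$visits$time_m
    qs <- unname(stats::quantile(tt, c(1, 2) / 3, type = 7))
    qs <- unique(qs[qs > 0 & qs < max(tt)])
    basis <- time_basis(c(0, max(max(tt), 1)), qs)
  }
  terms <- .assoc_active(spec$association)

  long <- list()
  for (k in spec$outcomes) {
    d <- build_design(x, k, basis = basis, covariates = spec$long_covariates)
    subj <- match(d$grouping, ids)
    ord <- order(subj)            # contiguous per-subject blocks
    counts <- tabulate(subj, n)
    long[[k]] <- list(X = d$X[ord, , drop = FALSE],
                      Z = d$Z[ord, , drop = FALSE],
                      y = d$y[ord], subj = subj[ord],
                      counts = counts, ends = cumsum(counts),
                      N = length(d$y), p = ncol(d$X), q = ncol(d$Z))
  }
  centers <- spec$centers
  if (is.null(centers))
    centers <- vapply(spec$outcomes, function(k) mean(long[[k]]$y),
                      numeric(1))

  Tm <- x$outcomes$followup_m
  delta <- x$outcomes$event
  W <- covariate_dummies(x$baseline, spec$surv_covariates)

  ev <- Tm[delta == 1]
  J <- spec$n_intervals
  cut <- numeric(0)
  if (J > 1 && length(ev) >= 2) {
    cut <- unique(unname(stats::quantile(ev, seq_len(J - 1) / J, type = 7)))
    cut <- cut[cut > 0 & cut < max(Tm)]
  }
  J <- length(cut) + 1L
  int_T <- findInterval(Tm, cut) + 1L
  d_j <- as.numeric(rowsum(as.numeric(delta), factor(int_T, levels = 1:J)))

  # quadrature grid over [0, T_i] for every subject
  qp <- spec$mcmc$quadrature_points
  gl <- lapply(seq_len(n), function(i) .quad_grid(Tm[i], cut, qp))
  q_counts <- vapply(gl, function(g) length(g$nodes), 1)
  subj_q <- rep(seq_len(n), q_counts)
  t_q <- unlist(lapply(gl, `[[`, "nodes"))
  w_q <- unlist(lapply(gl, `[[`, "weights"))
  int_q <- findInterval(t_q, cut) + 1L

  # term designs: columns follow the longitudinal X/Z layout so that the
  # same beta / b coefficients apply
  mk_term <- function(k, t, Wsub, mode) {
    # Wsub: covariate rows aligned with t
    Bv <- switch(mode, value = basis_eval(basis, t, "value"),
                 slope = basis_eval(basis, t, "deriv"),
                 area = basis_eval(basis, t, "integral"))
    pW <- ncol(long[[k]]$X) - 1L - basis$df
    Xm <- switch(mode,
                 value = cbind(1, Bv, Wsub),
                 slope = cbind(0, Bv, matrix(0, length(t), pW)),
                 area  = cbind(t, Bv, Wsub * t))
    Zm <- switch(mode, value = cbind(1, Bv), slope = cbind(0, Bv),
                 area = cbind(t, Bv))
    sc <- if (mode == "slope") 3 * .term_mmhg(mode) else 1
    shift <- switch(mode, value = rep(centers[[k]], length(t)),
                    slope = rep(0, length(t)), area = centers[[k]] * t)
    list(X = Xm, Z = Zm, sc = sc, shift = shift)
  }
  Wl <- covariate_dummies(x$baseline, spec$long_covariates)
  Wl_q <- Wl[subj_q, , drop = FALSE]
  term_q <- term_T <- list()
  for (k in spec$outcomes) {
    term_q[[k]] <- lapply(stats::setNames(terms, terms), function(m)
      mk_term(k, t_q, Wl_q, m))
    term_T[[k]] <- lapply(stats::setNames(terms, terms), function(m)
      mk_term(k, Tm, Wl, m))
  }

  structure(list(ids = ids, n = n, outcomes = spec$outcomes, long = long,
                 Tm = Tm, delta = delta, W = W, pw = ncol(W),
                 cutpoints = cut, J = J, int_T = int_T, d_j = d_j,
                 subj_q = subj_q, t_q = t_q, w_q = w_q, int_q = int_q,
                 q_counts = q_counts, q_ends = cumsum(q_counts),
                 M = length(t_q), terms = terms, term_q = term_q,
                 term_T = term_T, centers = centers, basis = basis,
                 structure = spec$association,
                 alpha_names = .alpha_names(spec$association,
                                            spec$outcomes)),
            class = "jm_design")
}

# ---------------------------------------------------------------------------
# likelihood pieces

# sums of v over contiguous per-subject blocks (ends/counts layout)
.blocksum <- function(v, ends, counts) {
  cs <- c(0, cumsum(v))
  cs[ends + 1] - cs[ends - counts + 1]
}

# per-subject longitudinal log-likelihood sums, given residuals
.long_ll_by_subject <- function(des_k, resid, sigma2, n) {
  ss <- .blocksum(resid^2, des_k$ends, des_k$counts)
  -0.5 * (des_k$counts * log(2 * pi * sigma2) + ss / sigma2)
}

# association functional values F_{k,term} at given term design, for one
# outcome's beta and random effects (matrix b: n x q)
.term_values <- function(tm, beta, b, subj) {
  drop(tm$X %*% beta) * tm$sc +
    rowSums(tm$Z * b[subj, , drop = FALSE]) * tm$sc - tm$shift
}

#' Joint log-likelihood contribution of one subject
#'
#' Returns the longitudinal Gaussian part and the survival part
#' (event indicator times log hazard at exit, minus the Gauss-Legendre
#' cumulative hazard), conditional on the subject's random effects.
#'
#' @param design a [jm_design()].
#' @param i subject index (position in `design$ids`).
#' @param params list with `beta` (named list per outcome), `b` (named
#'   list per outcome of n-by-q matrices), `sigma2` (named), `gamma`,
#'   `alpha` (named as `design$alpha_names`), `lambda` (length `design$J`).
#' @return named numeric: `longitudinal`, `survival`.
#' @export
subject_loglik <- function(design, i, params) {
  stopifnot(inherits(design, "jm_design"), i >= 1, i <= design$n)
  ll_long <- 0
  for (k in design$outcomes) {
    dk <- design$long[[k]]
    rows <- which(dk$subj == i)
    if (length(rows)) {
      mu <- drop(dk$X[rows, , drop = FALSE] %*% params$beta[[k]]) +
        drop(dk$Z[rows, , drop = FALSE] %*% params$b[[k]][i, ])
      ll_long <- ll_long + sum(stats::dnorm(dk$y[rows], mu,
                                            sqrt(params$sigma2[[k]]),
                                            log = TRUE))
    }
  }
  gw <- if (design$pw) drop(design$W[i, , drop = FALSE] %*% params$gamma) else 0
  term_T <- 0
  qrows <- which(design$subj_q == i)
  term_qv <- numeric(length(qrows))
  for (k in design$outcomes) for (m in design$terms) {
    a <- params$alpha[[paste(k, m, sep = "_")]]
    tmT <- design$term_T[[k]][[m]]
    fT <- drop(tmT$X[i, , drop = FALSE] %*% params$beta[[k]]) * tmT$sc +
      drop(tmT$Z[i, , drop = FALSE] %*% params$b[[k]][i, ]) * tmT$sc -
      tmT$shift[i]
    term_T <- term_T + a * fT
    tmq <- design$term_q[[k]][[m]]
    fq <- drop(tmq$X[qrows, , drop = FALSE] %*% params$beta[[k]]) * tmq$sc +
      drop(tmq$Z[qrows, , drop = FALSE] %*% params$b[[k]][i, ]) * tmq$sc -
      tmq$shift[qrows]
    term_qv <- term_qv + a * fq
  }
  loglam <- log(params$lambda)
  Lam <- sum(design$w_q[qrows] * params$lambda[design$int_q[qrows]] *
               exp(gw + term_qv))
  ll_surv <- design$delta[i] * (loglam[design$int_T[i]] + gw + term_T) - Lam
  c(longitudinal = ll_long, survival = unname(ll_surv))
}

# ---------------------------------------------------------------------------
# initialization

.jm_init <- function(x, design, spec) {
  init <- list(beta = list(), b = list(), sigma2 = c(), D = list(),
               prop = list())
  for (k in design$outcomes) {
    d <- build_design(x, k, basis = design$basis,
                      covariates = spec$long_covariates)
    f <- fit_lmm(d, random = "full")
    q <- design$long[[k]]$q
    init$beta[[k]] <- unname(f$beta)
    init$sigma2[k] <- f$sigma2_hat
    D0 <- f$D_hat + diag(1e-4, q)
    init$D[[k]] <- D0
    bmat <- matrix(0, design$n, q)
    rn <- rownames(f$blups)
    bmat[match(rn, design$ids), ] <- as.matrix(f$blups)
    init$b[[k]] <- bmat
    # proposal chols: fixed effects from the LMM curvature proxy,
    # random effects from the average conditional covariance
    XtX <- crossprod(design$long[[k]]$X)
    Vb <- tryCatch(solve(XtX / f$sigma2_hat), error = function(e)
      diag(0.01, ncol(XtX)))
    init$prop[[paste0("beta_", k)]] <- t(chol(.psd_part(Vb) + diag(1e-10, ncol(Vb))))
    ZtZ <- crossprod(design$long[[k]]$Z) / design$n  # avg per-subject info
    Vc <- solve(ZtZ / f$sigma2_hat + solve(D0))
    init$prop[[paste0("b_", k)]] <- t(chol(.psd_part(Vc) + diag(1e-10, q)))
  }
  if (design$pw) {
    cf <- tryCatch(cox_fit(x, design$W), error = function(e) NULL)
    if (!is.null(cf)) {
      init$gamma <- unname(cf$coef)
      Vg <- stats::vcov(cf$model)
      init$prop$gamma <- t(chol(.psd_part(Vg) + diag(1e-10, design$pw)))
    } else {
      init$gamma <- rep(0, design$pw)
      init$prop$gamma <- diag(0.1, design$pw)
    }
  } else {
    init$gamma <- numeric(0)
    init$prop$gamma <- matrix(0, 0, 0)
  }
  nA <- length(design$alpha_names)
  init$alpha <- stats::setNames(rep(0, nA), design$alpha_names)
  # precondition the alpha proposal by the empirical spread of each
  # association functional at the event times
  fs <- c()
  for (k in design$outcomes) for (m in design$terms) {
    Fv <- .term_values(design$term_T[[k]][[m]], init$beta[[k]],
                       init$b[[k]], seq_len(design$n))
    fs[paste(k, m, sep = "_")] <- max(stats::sd(Fv), 1e-3)
  }
  init$prop$alpha <- diag(0.4 / fs[design$alpha_names], nA)
  # crude interval-specific event rates
  expo <- as.numeric(rowsum(design$w_q, factor(design$int_q,
                                               levels = 1:design$J)))
  init$lambda <- pmax(design$d_j, 0.5) / pmax(expo, 1e-8)
  init
}

# ---------------------------------------------------------------------------
# the sampler

.run_chain <- function(design, spec, init, chain_seed, progress = FALSE) {
  set.seed(chain_seed)
  mc <- spec$mcmc; pr <- spec$priors
  n <- design$n; K <- design$outcomes
  M <- design$M
  total <- mc$total_iterations; burn <- mc$burn_in; thin <- mc$thin
  n_keep <- if (total > burn) (total - burn) %/% thin else 0L

  beta <- init$beta; b <- init$b; sigma2 <- init$sigma2
  Dl <- init$D; gamma <- init$gamma; alpha <- init$alpha
  lambda <- init$lambda

  # caches ------------------------------------------------------------
  resid <- list()
  for (k in K) {
    dk <- design$long[[k]]
    resid[[k]] <- dk$y - drop(dk$X %*% beta[[k]]) -
      rowSums(dk$Z * b[[k]][dk$subj, , drop = FALSE])
  }
  Fq <- FT <- list()
  upd_terms <- function(k) {
    for (m in design$terms) {
      Fq[[k]][[m]] <<- .term_values(design$term_q[[k]][[m]], beta[[k]],
                                    b[[k]], design$subj_q)
      FT[[k]][[m]] <<- .term_values(design$term_T[[k]][[m]], beta[[k]],
                                    b[[k]], seq_len(n))
    }
  }
  for (k in K) { Fq[[k]] <- list(); FT[[k]] <- list(); upd_terms(k) }
  termsum <- function(Flist) {
    s <- 0
    for (k in K) for (m in design$terms)
      s <- s + alpha[[paste(k, m, sep = "_")]] * Flist[[k]][[m]]
    s
  }
  gw_T <- if (design$pw) drop(design$W %*% gamma) else rep(0, n)
  gw_q <- gw_T[design$subj_q]
  ts_q <- termsum(Fq); ts_T <- termsum(FT)
  fint <- factor(design$int_q, levels = 1:design$J)
  w_q <- design$w_q; int_q <- design$int_q; int_T <- design$int_T
  delta <- design$delta; subj_q <- design$subj_q
  q_ends <- design$q_ends; q_counts <- design$q_counts
  hazexp <- exp(gw_q + ts_q)
  E_j <- as.numeric(rowsum(w_q * hazexp, fint))
  # per-iteration lambda caches (lambda is drawn once per sweep)
  wl <- w_q * lambda[int_q]
  loglam_T <- log(lambda)[int_T]

  surv_ll <- function(gw_q., ts_q., gw_T., ts_T.) {
    he <- exp(gw_q. + ts_q.)
    sum(delta * (loglam_T + gw_T. + ts_T.)) - sum(wl * he)
  }
  cur_surv <- surv_ll(gw_q, ts_q, gw_T, ts_T)

  # adaptive scales and covariances ------------------------------------
  ls <- list(alpha = 0, gamma = 0)
  for (k in K) { ls[[paste0("beta_", k)]] <- -1; ls[[paste0("b_", k)]] <- rep(-0.5, n) }
  # Haario-style running covariance per multivariate block, used to
  # refresh the proposal shape during burn-in (frozen afterwards)
  am <- list(); prop_L <- list()
  am_update <- function(nm, x) {
    a <- am[[nm]]
    if (is.null(a)) a <- list(mu = x, S = matrix(0, length(x), length(x)),
                              n = 0)
    a$n <- a$n + 1
    d0 <- x - a$mu
    a$mu <- a$mu + d0 / a$n
    a$S <- a$S + outer(d0, x - a$mu)
    am[[nm]] <<- a
  }
  am_refresh <- function(nm, d) {
    a <- am[[nm]]
    if (!is.null(a) && a$n > max(20, 4 * d)) {
      V <- a$S / (a$n - 1) + diag(1e-9, d)
      prop_L[[nm]] <<- t(chol(2.38^2 / d * V))
    }
  }
  get_L <- function(nm) prop_L[[nm]] %||% init$prop[[nm]]
  acc_n <- acc_d <- list()
  bump <- function(nm, a) {
    acc_n[[nm]] <<- (acc_n[[nm]] %||% 0) + a
    acc_d[[nm]] <<- (acc_d[[nm]] %||% 0) + 1
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  p_names <- c()
  for (k in K) p_names <- c(p_names, paste0(k, ".", colnames(design$long[[k]]$X)))
  for (k in K) p_names <- c(p_names, paste0("sigma_", k))
  for (k in K) p_names <- c(p_names,
                            paste0("sd_", k, "_b", 0:(design$long[[k]]$q - 1)))
  if (design$pw) p_names <- c(p_names, paste0("gamma.", colnames(design$W)))
  p_names <- c(p_names, paste0("alpha.", design$alpha_names),
               paste0("lambda.", seq_len(design$J)))
  draws <- matrix(NA_real_, n_keep, length(p_names),
                  dimnames = list(NULL, p_names))
  ll_pw <- matrix(NA_real_, n_keep, n)
  b_sum <- lapply(K, function(k) 0); names(b_sum) <- K
  keep_i <- 0L

  for (iter in seq_len(total)) {
    adapting <- mc$adapt && iter <= burn
    rm_step <- min(0.25, 2 / sqrt(iter))

    # (1) baseline heights: conjugate gamma
    lambda <- stats::rgamma(design$J, shape = pr$lambda_shape + design$d_j,
                            rate = pr$lambda_rate + E_j)
    lambda <- pmax(lambda, 1e-300)
    wl <- w_q * lambda[int_q]
    loglam_T <- log(lambda)[int_T]
    cur_surv <- surv_ll(gw_q, ts_q, gw_T, ts_T)

    # (2) residual variances: conjugate inverse-gamma
    for (k in K) {
      dk <- design$long[[k]]
      sigma2[k] <- 1 / stats::rgamma(1, shape = pr$sigma2_shape + dk$N / 2,
                                     rate = pr$sigma2_scale +
                                       sum(resid[[k]]^2) / 2)
    }

    # (3) random-effects covariance: conjugate inverse-Wishart per outcome
    for (k in K) {
      q <- design$long[[k]]$q
      S <- diag(q) + crossprod(b[[k]])
      Winv <- stats::rWishart(1, df = (q + 1) + n, Sigma = solve(S))[, , 1]
      Dl[[k]] <- solve(Winv)
    }

    # (4) fixed effects per outcome: block Metropolis
    for (k in K) {
      nm <- paste0("beta_", k)
      dk <- design$long[[k]]
      L <- get_L(nm)
      prop <- beta[[k]] + exp(ls[[nm]]) * drop(L %*% rnorm(dk$p))
      resid_p <- resid[[k]] - drop(dk$X %*% (prop - beta[[k]]))
      dlong <- -0.5 * (sum(resid_p^2) - sum(resid[[k]]^2)) / sigma2[k]
      Fq_p <- FT_p <- list()
      for (m in design$terms) {
        tmq <- design$term_q[[k]][[m]]; tmT <- design$term_T[[k]][[m]]
        Fq_p[[m]] <- Fq[[k]][[m]] + tmq$sc * drop(tmq$X %*% (prop - beta[[k]]))
        FT_p[[m]] <- FT[[k]][[m]] + tmT$sc * drop(tmT$X %*% (prop - beta[[k]]))
      }
      dalpha_q <- dalpha_T <- 0
      for (m in design$terms) {
        a <- alpha[[paste(k, m, sep = "_")]]
        dalpha_q <- dalpha_q + a * (Fq_p[[m]] - Fq[[k]][[m]])
        dalpha_T <- dalpha_T + a * (FT_p[[m]] - FT[[k]][[m]])
      }
      new_surv <- surv_ll(gw_q, ts_q + dalpha_q, gw_T, ts_T + dalpha_T)
      dprior <- -0.5 * pr$beta_precision * (sum(prop^2) - sum(beta[[k]]^2))
      lacc <- dlong + (new_surv - cur_surv) + dprior
      a01 <- is.finite(lacc) && log(runif(1)) < lacc
      if (a01) {
        beta[[k]] <- prop; resid[[k]] <- resid_p
        for (m in design$terms) { Fq[[k]][[m]] <- Fq_p[[m]]; FT[[k]][[m]] <- FT_p[[m]] }
        ts_q <- ts_q + dalpha_q; ts_T <- ts_T + dalpha_T
        cur_surv <- new_surv
      }
      bump(nm, as.numeric(a01))
      if (adapting) {
        ls[[nm]] <- ls[[nm]] + rm_step * (as.numeric(a01) - 0.234)
        am_update(nm, beta[[k]])
        if (iter %% 25 == 0) am_refresh(nm, dk$p)
      }
    }

    # (5) random effects: vectorized per-subject Metropolis, per outcome
    for (k in K) {
      nm <- paste0("b_", k)
      dk <- design$long[[k]]
      q <- dk$q
      eps <- matrix(rnorm(n * q), n, q) %*% t(init$prop[[nm]])
      prop <- b[[k]] + exp(ls[[nm]]) * eps
      dB <- prop - b[[k]]
      # longitudinal delta per subject
      dz <- rowSums(dk$Z * dB[dk$subj, , drop = FALSE])
      resid_p <- resid[[k]] - dz
      dss <- .blocksum(resid_p^2 - resid[[k]]^2, dk$ends, dk$counts)
      dlong <- -0.5 * dss / sigma2[k]
      # prior delta per subject
      Dinv <- solve(Dl[[k]])
      qf <- function(Bm) rowSums((Bm %*% Dinv) * Bm)
      dprior <- -0.5 * (qf(prop) - qf(b[[k]]))
      # survival delta per subject
      dts_q <- 0; dts_T <- 0
      for (m in design$terms) {
        a <- alpha[[paste(k, m, sep = "_")]]
        tmq <- design$term_q[[k]][[m]]; tmT <- design$term_T[[k]][[m]]
        dts_q <- dts_q + a * tmq$sc *
          rowSums(tmq$Z * dB[design$subj_q, , drop = FALSE])
        dts_T <- dts_T + a * tmT$sc * rowSums(tmT$Z * dB)
      }
      if (identical(dts_q, 0)) { dts_q <- numeric(M); dts_T <- numeric(n) }
      he_old <- exp(gw_q + ts_q)
      he_new <- exp(gw_q + ts_q + dts_q)
      Lam_old <- .blocksum(wl * he_old, q_ends, q_counts)
      Lam_new <- .blocksum(wl * he_new, q_ends, q_counts)
      dsurv <- design$delta * dts_T - (Lam_new - Lam_old)
      lacc <- dlong + dprior + dsurv
      acc <- is.finite(lacc) & log(runif(n)) < lacc
      if (any(acc)) {
        b[[k]][acc, ] <- prop[acc, ]
        sel <- acc[dk$subj]
        resid[[k]][sel] <- resid_p[sel]
        selq <- acc[design$subj_q]
        for (m in design$terms) {
          tmq <- design$term_q[[k]][[m]]; tmT <- design$term_T[[k]][[m]]
          dFq <- tmq$sc * rowSums(tmq$Z * dB[design$subj_q, , drop = FALSE])
          dFT <- tmT$sc * rowSums(tmT$Z * dB)
          Fq[[k]][[m]][selq] <- Fq[[k]][[m]][selq] + dFq[selq]
          FT[[k]][[m]][acc] <- FT[[k]][[m]][acc] + dFT[acc]
        }
        ts_q[selq] <- ts_q[selq] + dts_q[selq]
        ts_T[acc] <- ts_T[acc] + dts_T[acc]
        cur_surv <- surv_ll(gw_q, ts_q, gw_T, ts_T)
      }
      bump(nm, mean(acc))
      if (adapting)
        ls[[nm]] <- ls[[nm]] + rm_step * (as.numeric(acc) - 0.234)
    }

    # (6) survival coefficients: block Metropolis
    if (design$pw) {
      prop <- gamma + exp(ls$gamma) * drop(get_L("gamma") %*% rnorm(design$pw))
      gw_T_p <- drop(design$W %*% prop)
      gw_q_p <- gw_T_p[design$subj_q]
      new_surv <- surv_ll(gw_q_p, ts_q, gw_T_p, ts_T)
      dprior <- -0.5 * pr$gamma_precision * (sum(prop^2) - sum(gamma^2))
      lacc <- new_surv - cur_surv + dprior
      a01 <- is.finite(lacc) && log(runif(1)) < lacc
      if (a01) { gamma <- prop; gw_T <- gw_T_p; gw_q <- gw_q_p; cur_surv <- new_surv }
      bump("gamma", as.numeric(a01))
      if (adapting) {
        ls$gamma <- ls$gamma + rm_step * (as.numeric(a01) - 0.234)
        am_update("gamma", gamma)
        if (iter %% 25 == 0) am_refresh("gamma", design$pw)
      }
    }

    # (7) association coefficients: block Metropolis.  The hazard is
    # linear in alpha so the cached functionals are reused directly;
    # the block is cheap and strongly correlated a posteriori, so it is
    # refreshed several times per sweep.
    nA <- length(alpha)
    if (nA) for (rep_a in 1:3) {
      prop <- alpha + exp(ls$alpha) * drop(get_L("alpha") %*% rnorm(nA))
      names(prop) <- names(alpha)
      ts_q_p <- numeric(M); ts_T_p <- numeric(n)
      for (k in K) for (m in design$terms) {
        a <- prop[[paste(k, m, sep = "_")]]
        ts_q_p <- ts_q_p + a * Fq[[k]][[m]]
        ts_T_p <- ts_T_p + a * FT[[k]][[m]]
      }
      new_surv <- surv_ll(gw_q, ts_q_p, gw_T, ts_T_p)
      dprior <- -0.5 * pr$alpha_precision * (sum(prop^2) - sum(alpha^2))
      lacc <- new_surv - cur_surv + dprior
      a01 <- is.finite(lacc) && log(runif(1)) < lacc
      if (a01) { alpha <- prop; ts_q <- ts_q_p; ts_T <- ts_T_p; cur_surv <- new_surv }
      bump("alpha", as.numeric(a01))
      if (adapting) {
        ls$alpha <- ls$alpha + rm_step * (as.numeric(a01) - 0.234)
        am_update("alpha", unname(alpha))
        if (iter %% 25 == 0 && rep_a == 1) am_refresh("alpha", nA)
      }
    }

    # refresh E_j for the next lambda draw
    hazexp <- exp(gw_q + ts_q)
    E_j <- as.numeric(rowsum(w_q * hazexp, fint))

    # (8) record
    if (iter > burn && (iter - burn) %% thin == 0) {
      keep_i <- keep_i + 1L
      row <- c()
      for (k in K) row <- c(row, beta[[k]])
      for (k in K) row <- c(row, sqrt(sigma2[k]))
      for (k in K) row <- c(row, sqrt(diag(Dl[[k]])))
      if (design$pw) row <- c(row, gamma)
      row <- c(row, alpha, lambda)
      draws[keep_i, ] <- row
      ll_long_i <- 0
      for (k in K)
        ll_long_i <- ll_long_i +
          .long_ll_by_subject(design$long[[k]], resid[[k]], sigma2[k], n)
      Lam_i <- .blocksum(wl * hazexp, q_ends, q_counts)
      ll_surv_i <- delta * (loglam_T + gw_T + ts_T) - Lam_i
      ll_pw[keep_i, ] <- ll_long_i + ll_surv_i
      for (k in K) b_sum[[k]] <- b_sum[[k]] + b[[k]]
    }
  }

  acc_rate <- mapply(function(a, d) a / d, acc_n, acc_d)
  list(draws = draws, ll_pointwise = ll_pw,
       b_mean = if (n_keep) lapply(b_sum, function(s) s / n_keep) else NULL,
       acceptance = acc_rate, scales = ls, n_keep = n_keep)
}

#' Fit the Bayesian joint model
#'
#' Initializes from separate linear-mixed and Cox fits (association
#' coefficients start at zero, baseline heights at crude interval event
#' rates) and runs `chains` Metropolis-within-Gibbs chains.  Draws are
#' bitwise-reproducible given the seed and chain index.
#'
#' @param x a [cohort()].
#' @param spec a [joint_model_spec()].
#' @param progress unused placeholder.
#' @return object of class `jm_fit`: per-chain draw matrices, per-draw
#'   subject log-likelihood contributions, posterior-mean random effects,
#'   acceptance rates, the design and the spec.
#' @export
fit_joint <- function(x, spec, progress = FALSE) {
  design <- jm_design(x, spec)
  init <- .jm_init(x, design, spec)
  chains <- vector("list", spec$mcmc$chains)
  for (ch in seq_len(spec$mcmc$chains)) {
    chains[[ch]] <- .run_chain(design, spec, init,
                               .substream(spec$mcmc$seed,
                                          paste0("chain", ch)))
  }
  acc <- chains[[1]]$acceptance
  if (length(acc) && (any(acc < 0.05) || any(acc > 0.95)))
    warning("MCMC acceptance rate outside [0.05, 0.95] for block(s): ",
            paste(names(acc)[acc < 0.05 | acc > 0.95], collapse = ", "))
  structure(list(chains = chains, design = design, spec = spec,
                 init = init,
                 n_keep = chains[[1]]$n_keep,
                 param_names = colnames(chains[[1]]$draws)),
            class = "jm_fit")
}

#' @export
print.jm_fit <- function(x, ...) {
  cat("Bayesian joint model fit:", x$spec$association, "association,",
      length(x$chains), "chain(s) x", x$n_keep, "retained draws\n")
  cat("  outcomes:", paste(x$design$outcomes, collapse = ", "),
      "| subjects:", x$design$n, "| events:", sum(x$design$delta), "\n")
  invisible(x)
}

# stack one parameter across chains into a matrix (draws x chains)
.param_chains <- function(fit, name) {
  m <- vapply(fit$chains, function(ch) ch$draws[, name],
              numeric(fit$n_keep))
  if (is.null(dim(m))) m <- matrix(m, nrow = fit$n_keep)
  m
}

#' Summarize a joint model fit
#'
#' Pooled-chain posterior means and percentile 95% credible intervals,
#' with split-Rhat and effective sample size per parameter; survival and
#' association coefficients additionally reported as adjusted hazard
#' ratios (exponentiated).
#'
#' @param object a [fit_joint()] result.
#' @param ... unused.
#' @return data.frame of class `jm_summary`.
#' @export
summary.jm_fit <- function(object, ...) {
  if (object$n_keep < 2) stop("need at least two retained draws to summarize")
  nm <- object$param_names
  rows <- lapply(nm, function(p) {
    m <- .param_chains(object, p)
    pool <- as.vector(m)
    ci <- unname(stats::quantile(pool, c(0.025, 0.975), type = 7))
    rh <- split_rhat(m)
    es <- ess_mean(m)
    hr <- grepl("^(gamma|alpha)\\.", p)
    data.frame(parameter = p, mean = mean(pool), lower = ci[1],
               upper = ci[2],
               ahr = if (hr) exp(mean(pool)) else NA_real_,
               ahr_lower = if (hr) exp(ci[1]) else NA_real_,
               ahr_upper = if (hr) exp(ci[2]) else NA_real_,
               rhat = rh, ess = es)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("jm_summary", "data.frame")
  out
}

#' @export
print.jm_summary <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], function(v) round(v, 3))
  print(y, row.names = FALSE)
  invisible(x)
}
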