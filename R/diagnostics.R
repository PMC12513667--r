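# MCMC convergence diagnostics (split rank-normalized Rhat, autocorrelation
# ESS with initial-monotone truncation) and Bayesian model comparison
# (DIC, WAIC) from per-draw subject log-likelihood contributions.

# split each column (chain) of m into two half-chains
.split_chains <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  h <- n %/% 2
  if (h < 2) return(m)
  do.call(cbind, lapply(seq_len(ncol(m)), function(j)
    cbind(m[1:h, j], m[(n - h + 1):n, j])))
}

# rank-normalize pooled draws, preserving the chain layout
.rank_normalize <- function(m) {
  r <- rank(as.vector(m), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

#' Split rank-normalized potential scale reduction factor
#'
#' @param m matrix of draws, one column per chain (columns are split in
#'   half internally, so a single chain is diagnosable too).
#' @return scalar Rhat; 1 by convention when the draws are constant.
#' @export
split_rhat <- function(m) {
  m <- .split_chains(as.matrix(m))
  if (stats::sd(as.vector(m)) < 1e-12) return(1)
  z <- .rank_normalize(m)
  n <- nrow(z); cm <- colMeans(z)
  W <- mean(apply(z, 2, stats::var))
  B <- n * stats::var(cm)
  vp <- (n - 1) / n * W + B / n
  sqrt(vp / W)
}

#' Effective sample size of the mean
#'
#' Autocorrelation-based ESS using Geyer's initial-monotone positive
#' sequence truncation, combined across (split) chains.
#'
#' @param m matrix of draws, one column per chain.
#' @return scalar ESS; `NA` for constant draws (degenerate chain).
#' @export
ess_mean <- function(m) {
  m <- .split_chains(as.matrix(m))
  n <- nrow(m); C <- ncol(m)
  if (stats::sd(as.vector(m)) < 1e-12) return(NA_real_)
  ac <- vapply(seq_len(C), function(j)
    stats::acf(m[, j], lag.max = n - 1, plot = FALSE,
               type = "covariance")$acf[, 1, 1], numeric(n))
  W <- mean(ac[1, ]) * n / (n - 1)          # mean within-chain variance
  B_over_n <- if (C > 1) stats::var(colMeans(m)) else 0
  vp <- (n - 1) / n * W + B_over_n          # marginal variance estimate
  rho <- 1 - (W - rowMeans(ac)) / vp
  rho[1] <- 1
  # Geyer: sum autocorrelations in pairs while the pair sums stay
  # positive and non-increasing
  tmax <- 2 * ((n - 1) %/% 2)
  pair <- rho[seq(1, tmax, by = 2)] + rho[seq(2, tmax + 1, by = 2)]
  bad <- which(pair < 0)
  kmax <- if (length(bad)) bad[1] - 1 else length(pair)
  if (kmax > 1) pair[1:kmax] <- cummin(pair[1:kmax])
  tau <- -1 + 2 * sum(pair[seq_len(kmax)])
  max(C * n / max(tau, 1 / (C * n)), 0)
}

#' Convergence report for a joint model fit
#'
#' Per-parameter split rank-normalized Rhat and effective sample size,
#' with a flag for Rhat above 1.01.
#'
#' @param fit a [fit_joint()] result with at least two chains and at
#'   least four retained draws per chain.
#' @return data.frame of class `convergence_report`.
#' @export
convergence_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "jm_fit"))
  if (length(fit$chains) < 2)
    stop("Rhat requires at least two chains")
  if (fit$n_keep < 4) stop("need at least four retained draws per chain")
  rows <- lapply(fit$param_names, function(p) {
    m <- .param_chains(fit, p)
    data.frame(parameter = p, rhat = split_rhat(m), ess = ess_mean(m))
  })
  out <- do.call(rbind, rows)
  out$flag <- !is.na(out$rhat) & out$rhat > 1.01
  class(out) <- c("convergence_report", "data.frame")
  out
}

# pooled per-draw subject log-likelihood matrix (draws x subjects)
.ll_matrix <- function(fit) {
  do.call(rbind, lapply(fit$chains, `[[`, "ll_pointwise"))
}

# joint log-likelihood at a parameter point (vectorized over subjects)
.total_ll <- function(design, params) {
  sum(vapply(seq_len(design$n),
             function(i) sum(subject_loglik(design, i, params)), numeric(1)))
}

# plug-in parameter point: posterior means of everything including the
# subject random effects
.posterior_mean_params <- function(fit) {
  des <- fit$design
  pm <- colMeans(do.call(rbind, lapply(fit$chains, `[[`, "draws")))
  beta <- b <- list(); sigma2 <- c()
  for (k in des$outcomes) {
    beta[[k]] <- unname(pm[paste0(k, ".", colnames(des$long[[k]]$X))])
    sigma2[k] <- unname(pm[paste0("sigma_", k)])^2
    bm <- Reduce(`+`, lapply(fit$chains, function(ch) ch$b_mean[[k]])) /
      length(fit$chains)
    b[[k]] <- bm
  }
  gamma <- if (des$pw) unname(pm[paste0("gamma.", colnames(des$W))]) else numeric(0)
  alpha <- pm[paste0("alpha.", des$alpha_names)]
  names(alpha) <- des$alpha_names
  lambda <- unname(pm[paste0("lambda.", seq_len(des$J))])
  list(beta = beta, b = b, sigma2 = sigma2, gamma = gamma, alpha = alpha,
       lambda = lambda)
}

#' Deviance and widely applicable information criteria
#'
#' WAIC is computed from the per-draw, per-subject log-likelihood
#' contributions: \eqn{-2(\mathrm{lppd} - p_\mathrm{waic})} with
#' \eqn{p_\mathrm{waic}} the summed draw-variances.  DIC uses the plug-in
#' deviance at the posterior mean of all parameters (random effects
#' included): \eqn{\mathrm{DIC} = \bar D + p_D},
#' \eqn{p_D = \bar D - D(\hat\theta)}.
#'
#' @param fit a [fit_joint()] result.
#' @return list with `dic`, `waic`, `p_d`, `p_waic`, `lppd`,
#'   `mean_deviance`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "jm_fit"))
  ll <- .ll_matrix(fit)
  if (!nrow(ll)) stop("no retained draws")
  w <- waic_from_loglik(ll)
  dbar <- -2 * mean(rowSums(ll))
  dhat <- -2 * .total_ll(fit$design, .posterior_mean_params(fit))
  p_d <- dbar - dhat
  list(dic = dbar + p_d, waic = w$waic, p_d = p_d, p_waic = w$p_waic,
       lppd = w$lppd, mean_deviance = dbar)
}

#' WAIC from a pointwise log-likelihood matrix
#'
#' @param ll matrix of per-draw (rows), per-observation (columns)
#'   log-likelihood contributions.
#' @return list with `waic`, `lppd`, `p_waic`.
#' @export
waic_from_loglik <- function(ll) {
  ll <- as.matrix(ll)
  if (any(!is.finite(ll)))
    stop("non-finite pointwise log-likelihood for observation(s): ",
         paste(which(apply(!is.finite(ll), 2, any)), collapse = ", "))
  lse <- apply(ll, 2, function(v) {
    mx <- max(v); mx + log(mean(exp(v - mx)))
  })
  lppd <- sum(lse)
  p_waic <- sum(apply(ll, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Compare fitted joint models by WAIC and DIC
#'
#' Models must be fitted to the same cohort.  The table is sorted by WAIC
#' (the primary criterion); disagreement with the DIC ranking is flagged.
#'
#' @param fits named list of [fit_joint()] results.
#' @return list with `table` (label, waic, dic, ranked by WAIC) and
#'   `disagreement`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2)
  dg <- vapply(fits, function(f) sum(f$design$Tm) + f$design$n, numeric(1))
  if (max(abs(dg - dg[1])) > 1e-8)
    stop("fits are not on the same cohort")
  labs <- if (!is.null(names(fits))) names(fits)
          else vapply(fits, function(f) f$spec$association, "")
  ic <- lapply(fits, information_criteria)
  tab <- data.frame(model = labs,
                    waic = vapply(ic, `[[`, numeric(1), "waic"),
                    dic = vapply(ic, `[[`, numeric(1), "dic"))
  tab <- tab[order(tab$waic), ]
  rownames(tab) <- NULL
  list(table = tab,
       disagreement = !identical(order(tab$waic), order(tab$dic)))
}
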