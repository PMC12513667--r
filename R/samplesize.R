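# Closed-form sample-size calculators for the two study outcomes and the
# contingency adjustment.

.z_pair <- function(alpha, power, z_method) {
  if (z_method == "exact")
    c(za = stats::qnorm(1 - alpha / 2), zb = stats::qnorm(power))
  else
    c(za = round(stats::qnorm(1 - alpha / 2), 2),
      zb = round(stats::qnorm(power), 2))
}

#' Sample size for a repeated-measures (longitudinal) outcome
#'
#' Evaluates
#' \deqn{n = \frac{4(z_{\alpha/2}+z_\beta)^2\,\sigma^2\,(1+(J-1)\rho)}{J\,\delta^2}}
#' and rounds up.  `z_method = "rounded"` (default) uses the conventional
#' two-decimal normal quantiles (1.96, 0.84 for 5% / 80%), the convention
#' under which the design arithmetic lands on 393 and 249; `"exact"` uses full
#' quantiles (0.8416 for 80% power).
#'
#' @param sigma2 outcome variance.
#' @param delta effect size to detect.
#' @param J number of repeated measurements per subject.
#' @param rho within-subject correlation (0 <= rho < 1).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param z_method `"rounded"` or `"exact"`.
#' @return list with `n` (integer), `n_raw`, `z_alpha`, `z_beta`.
#' @export
n_longitudinal <- function(sigma2, delta = 0.8, J = 15, rho = 0.5,
                           alpha = 0.05, power = 0.80,
                           z_method = c("rounded", "exact")) {
  z_method <- match.arg(z_method)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, J >= 1,
            rho >= 0, rho < 1, delta > 0, sigma2 > 0)
  z <- .z_pair(alpha, power, z_method)
  n_raw <- 4 * (z["za"] + z["zb"])^2 * sigma2 * (1 + (J - 1) * rho) /
    (J * delta^2)
  list(n = max(1L, as.integer(ceiling(n_raw - 1e-9))),
       n_raw = unname(n_raw),
       z_alpha = unname(z["za"]), z_beta = unname(z["zb"]))
}

#' Sample size for the survival outcome
#'
#' Evaluates \eqn{n = 4(z_{\alpha/2}+z_\beta)^2 / (P\,\theta^2)} where
#' `P` is the anticipated event probability and `theta` the log hazard
#' ratio to detect, rounding up.
#'
#' @param P anticipated event probability (0 < P < 1).
#' @param theta log hazard ratio (non-zero).
#' @inheritParams n_longitudinal
#' @return list with `n`, `n_raw`, `z_alpha`, `z_beta`.
#' @export
n_survival <- function(P = 0.176, theta = 0.69, alpha = 0.05, power = 0.80,
                       z_method = c("rounded", "exact")) {
  z_method <- match.arg(z_method)
  stopifnot(P > 0, P < 1, alpha > 0, alpha < 1, power > 0, power < 1)
  if (theta == 0) stop("theta (log hazard ratio) must be non-zero")
  z <- .z_pair(alpha, power, z_method)
  n_raw <- 4 * (z["za"] + z["zb"])^2 / (P * theta^2)
  list(n = max(1L, as.integer(ceiling(n_raw - 1e-9))),
       n_raw = unname(n_raw),
       z_alpha = unname(z["za"]), z_beta = unname(z["zb"]))
}

#' Final sample size with contingency
#'
#' The largest candidate size inflated by the contingency fraction,
#' rounded up.
#'
#' @param candidates numeric vector of candidate sizes.
#' @param contingency non-negative fraction (e.g. 0.10).
#' @return integer.
#' @export
final_n <- function(candidates, contingency = 0.10) {
  stopifnot(length(candidates) >= 1, contingency >= 0)
  as.integer(ceiling(max(candidates) * (1 + contingency) - 1e-9))
}
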