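# Shared hazard machinery: association-term evaluation, piecewise-constant
# baseline, and Gauss-Legendre cumulative hazards.  The synthetic generator
# and the MCMC likelihood both go through these evaluators, so simulated
# event times and fitted cumulative hazards are computed by the same code.

.assoc_structures <- c("current_value", "slope", "value_and_slope",
                       "area", "area_and_value")

# active functional(s) of the latent trajectory for each structure
.assoc_active <- function(structure) {
  switch(structure,
         current_value  = "value",
         slope          = "slope",
         value_and_slope = c("value", "slope"),
         area           = "area",
         area_and_value = c("area", "value"),
         stop("unknown association structure: ", structure))
}

# names of the association coefficients, outcome-major
.alpha_names <- function(structure, outcomes = c("sbp", "dbp")) {
  terms <- .assoc_active(structure)
  as.vector(t(outer(outcomes, terms, paste, sep = "_")))
}

#' Evaluate a latent trajectory, its slope, or its area
#'
#' The latent (error-free) trajectory of one outcome for one subject is
#' \eqn{\eta(t) = a + B(t)'\theta}, where \eqn{a} collects the fixed
#' intercept, the subject's covariate effects and the random intercept, and
#' \eqn{\theta} collects the fixed-plus-random coefficients of the spline
#' time basis.  `mode = "slope"` returns the *quarterly* rate of change
#' (3 times the per-month derivative, the scale on which association
#' coefficients for the slope are reported); `mode = "area"` returns
#' \eqn{\int_0^t (\eta(s) - c)\,ds} with centering constant `center`.
#' `mode = "value"` returns \eqn{\eta(t) - c \cdot \mathrm{center\_value}}
#' only when `centered = TRUE`; by default the raw value.
#'
#' @param t times in months.
#' @param a scalar: intercept plus covariate and random-intercept effects
#'   (internal outcome scale, i.e. mmHg/10).
#' @param theta coefficients of the time-basis columns (fixed + random).
#' @param basis a [time_basis()].
#' @param mode `"value"`, `"slope"`, or `"area"`.
#' @param center centering constant subtracted from the trajectory before
#'   integrating (area mode) -- and from the value when `centered = TRUE`.
#' @param centered logical; subtract `center` in value mode.
#' @return numeric vector, one element per time.
#' @export
eta_eval <- function(t, a, theta, basis, mode = c("value", "slope", "area"),
                     center = 0, centered = FALSE) {
  mode <- match.arg(mode)
  B <- basis_eval(basis, t, switch(mode, value = "value", slope = "deriv",
                                   area = "integral"))
  v <- drop(B %*% theta)
  switch(mode,
         value = a + v - (if (centered) center else 0),
         slope = 3 * v,
         area  = a * t + v - center * t)
}

# log hazard for one subject at times t.
#   eta_pars: list per outcome of list(a =, theta =)
#   centers:  named per outcome
#   alpha:    named as .alpha_names(structure)
.log_hazard_subject <- function(t, bh, lin_pred_w, alpha, structure,
                                eta_pars, centers, basis) {
  lh <- .log_baseline(bh, t) + lin_pred_w
  for (k in names(eta_pars)) {
    p <- eta_pars[[k]]
    for (term in .assoc_active(structure)) {
      f <- eta_eval(t, p$a, p$theta, basis, mode = term,
                    center = centers[[k]], centered = TRUE) *
        .term_mmhg(term)
      lh <- lh + alpha[[paste(k, term, sep = "_")]] * f
    }
  }
  lh
}

# the slope association term is expressed in mmHg per quarter (the scale
# on which its hazard ratios are reported); value and area stay on the
# internal mmHg/10 scale, whose unit the reporting layer documents
.term_mmhg <- function(mode) if (mode == "slope") 10 else 1

# piecewise-constant baseline: heights[j] on [bounds[j], bounds[j+1]); the
# last interval extends to +Inf.  cutpoints are the interior boundaries.
.log_baseline <- function(bh, t) {
  j <- findInterval(t, bh$cutpoints) + 1L
  log(bh$heights)[j]
}

.bh_validate <- function(bh) {
  stopifnot(is.numeric(bh$heights), all(bh$heights > 0),
            length(bh$heights) == length(bh$cutpoints) + 1L)
  if (length(bh$cutpoints))
    stopifnot(all(bh$cutpoints > 0), !is.unsorted(bh$cutpoints, strictly = TRUE))
  bh
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch, cached
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  w <- 2 * e$vectors[1, ]^2
  ord <- order(e$values)
  out <- list(nodes = e$values[ord], weights = w[ord])
  .gl_cache[[key]] <- out
  out
}

# quadrature nodes and weights covering [0, t] split at baseline cutpoints;
# segments longer than 30 months are subdivided so the Gauss-Legendre rule
# keeps full accuracy over long final intervals.  Returns list(nodes,
# weights, interval) where interval indexes heights.
.quad_grid <- function(t, cutpoints, q) {
  bounds <- unique(c(0, cutpoints[cutpoints < t], t))
  len <- diff(bounds)
  if (any(len > 30)) {
    bounds <- unique(sort(unlist(lapply(seq_along(len), function(j)
      seq(bounds[j], bounds[j + 1], length.out = ceiling(len[j] / 30) + 1)))))
  }
  gl <- .gauss_legendre(q)
  nodes <- weights <- interval <- numeric(0)
  for (j in seq_len(length(bounds) - 1)) {
    lo <- bounds[j]; hi <- bounds[j + 1]
    nodes <- c(nodes, (hi - lo) / 2 * gl$nodes + (hi + lo) / 2)
    weights <- c(weights, (hi - lo) / 2 * gl$weights)
  }
  interval <- findInterval(nodes, cutpoints) + 1L
  list(nodes = nodes, weights = weights, interval = interval)
}

# cumulative hazard at time t for one subject (quadrature evaluator shared
# by the event-time simulator and the fitting code)
.cum_hazard_subject <- function(t, bh, lin_pred_w, alpha, structure,
                                eta_pars, centers, basis, q = 15) {
  if (t <= 0) return(0)
  g <- .quad_grid(t, bh$cutpoints, q)
  lh <- .log_hazard_subject(g$nodes, bh, lin_pred_w, alpha, structure,
                            eta_pars, centers, basis)
  sum(g$weights * exp(lh))
}

#' Simulate one event time by inverting the cumulative hazard
#'
#' Solves \eqn{\Lambda_i(t^*) = -\log u} for \eqn{t^*} by bracketing over
#' the baseline intervals followed by root refinement, using the same
#' Gauss-Legendre cumulative-hazard evaluator as the model likelihood.
#' Returns `Inf` when the total hazard over `(0, horizon]` is insufficient
#' (the subject survives the horizon).
#'
#' @param u uniform variate in (0,1).
#' @param bh baseline hazard: list with `cutpoints` and `heights`.
#' @param lin_pred_w scalar \eqn{\gamma'w_i}.
#' @param alpha named association coefficients (see [joint_model_spec()]).
#' @param structure association structure name.
#' @param eta_pars per-outcome list of `a` (intercept part) and `theta`
#'   (time-basis coefficients), on the internal mmHg/10 scale.
#' @param centers named per-outcome centering constants.
#' @param basis a [time_basis()].
#' @param horizon administrative horizon in months.
#' @param q Gauss-Legendre nodes per baseline interval.
#' @return event time in months, or `Inf`.
#' @export
simulate_event_time <- function(u, bh, lin_pred_w, alpha, structure,
                                eta_pars, centers, basis, horizon = 120,
                                q = 15) {
  stopifnot(u > 0, u < 1)
  target <- -log(u)
  Lam <- function(t) .cum_hazard_subject(t, bh, lin_pred_w, alpha, structure,
                                         eta_pars, centers, basis, q)
  if (Lam(horizon) < target) return(Inf)
  r <- stats::uniroot(function(t) Lam(t) - target, interval = c(0, horizon),
                      tol = 1e-10)
  r$root
}
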