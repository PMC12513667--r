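#' Natural cubic spline time basis with analytic derivative and integral
#'
#' Constructs a natural cubic spline basis for the time axis, used for the
#' fixed and random time effects of the longitudinal submodels and for the
#' slope and area functionals of the association structure.  The basis is
#' built from truncated cubic powers on a unit-scaled time axis, so its
#' first derivative and running integral are available in closed form --
#' a requirement for the slope and area association terms, which must be
#' evaluated exactly inside the hazard.
#'
#' With boundary knots \eqn{(L, R)} and \eqn{K} interior knots the basis has
#' \eqn{K + 1} columns (an intercept is *not* included).  Beyond the right
#' boundary the spline continues linearly (the natural-spline tail), which
#' the package uses deliberately when a subject's event time exceeds the
#' last observed visit time.
#'
#' @param boundary numeric length-2, boundary knots in months (default
#'   `c(0, 120)`).
#' @param interior numeric vector of interior knots in months, strictly
#'   inside `boundary`.  Default `c(40, 80)` gives the 3-column basis used
#'   throughout the package.
#' @return an object of class `time_basis`.
#' @examples
#' tb <- time_basis(c(0, 120), c(40, 80))
#' basis_eval(tb, c(0, 6, 60))
#' @export
time_basis <- function(boundary = c(0, 120), interior = c(40, 80)) {
  stopifnot(length(boundary) == 2, boundary[1] < boundary[2])
  if (length(interior) > 0) {
    stopifnot(all(interior > boundary[1]), all(interior < boundary[2]),
              !is.unsorted(interior, strictly = TRUE))
  }
  # all knots on the unit-scaled axis u = (t - L) / (R - L)
  L <- boundary[1]; R <- boundary[2]
  u_knots <- (c(L, interior, R) - L) / (R - L)   # all knots, unit scale
  structure(list(boundary = boundary, interior = interior,
                 scale = R - L, u_knots = u_knots,
                 df = length(interior) + 1L),
            class = "time_basis")
}

#' @export
print.time_basis <- function(x, ...) {
  cat("natural cubic spline time basis:", x$df, "columns\n")
  cat("  boundary knots:", x$boundary[1], "-", x$boundary[2], "months\n")
  cat("  interior knots:", if (length(x$interior)) paste(x$interior, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

# truncated cubic power and its derivative / antiderivative, on the u axis
.tp3  <- function(u, a) { d <- pmax(u - a, 0); d^3 }
.tp3d <- function(u, a) { d <- pmax(u - a, 0); 3 * d^2 }
.tp3i <- function(u, a) { d <- pmax(u - a, 0); d^4 / 4 }

#' Evaluate a time basis, its derivative, or its running integral
#'
#' @param basis a [time_basis()] object.
#' @param t numeric vector of times in months (any non-negative value;
#'   times past the right boundary use the natural linear tail).
#' @param mode `"value"` for the basis itself, `"deriv"` for its first
#'   derivative per month, `"integral"` for \eqn{\int_0^t B(s)\,ds}
#'   (month units).
#' @return numeric matrix, `length(t)` rows by `df(basis)` columns.
#' @export
basis_eval <- function(basis, t, mode = c("value", "deriv", "integral")) {
  mode <- match.arg(mode)
  stopifnot(inherits(basis, "time_basis"))
  L <- basis$boundary[1]; S <- basis$scale
  u <- (t - L) / S
  kn <- basis$u_knots
  K <- length(kn)                      # interior knots + right boundary
  uR <- kn[K]
  fn <- switch(mode, value = .tp3, deriv = .tp3d, integral = .tp3i)
  # d_k(u) = [ (u - k_k)_+^3 - (u - uR)_+^3 ] / (uR - k_k); natural basis
  # columns are {u, d_1 - d_{K-1}, ..., d_{K-2} - d_{K-1}}
  dk <- function(k) (fn(u, kn[k]) - fn(u, uR)) / (uR - kn[k])
  cols <- vector("list", basis$df)
  cols[[1]] <- switch(mode, value = u, deriv = rep(1, length(u)),
                      integral = u^2 / 2)
  if (K >= 2) {
    dlast <- dk(K - 1)
    for (k in seq_len(K - 2)) cols[[k + 1]] <- dk(k) - dlast
  }
  out <- do.call(cbind, cols)
  # convert u-axis calculus back to months
  out <- switch(mode, value = out, deriv = out / S, integral = out * S)
  # integral is taken from t = 0, not from the left boundary; with L = 0
  # (the package default) the two coincide.  For L != 0 shift by the
  # constant segment [0, L] where the basis is linear below the boundary.
  if (mode == "integral" && L != 0) {
    stop("time_basis integrals require a left boundary at 0")
  }
  colnames(out) <- paste0("time", seq_len(basis$df))
  out
}
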