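#' Input splines
#'
#' The time-dependent input of an ODE model is represented by a natural cubic
#' spline through a set of control points `v_1, ..., v_N` at fixed knots
#' `t_1, ..., t_N` (the input measurement times).  When `log_scale` is set the
#' control points live on the log10-input scale and the input value is
#' `10^S(t)`, which guarantees strict positivity of the reconstructed input
#' between the measured points.  The control points are the free parameters of
#' the joint ("comprehensive") estimation.
#'
#' Outside `[t_1, t_N]` the spline is continued as a constant at the boundary
#' value, so that an ODE solver may step marginally outside the data window.
#'
#' @param knots strictly increasing vector of knot times.
#' @param control_points spline values at the knots (log10-input scale when
#'   `log_scale = TRUE`).
#' @param degree polynomial degree; only cubic (`3`) splines are supported.
#' @param lambda curvature-smoothing parameter associated with the spline
#'   (metadata; the spline itself always interpolates its control points).
#' @param log_scale logical; if `TRUE`, [evaluate_input()] returns
#'   `10^S(t)`.
#' @return An object of class `input_spline`.
#' @seealso [interpolating_spline()], [smoothing_spline()],
#'   [evaluate_input()], [curvature_penalty()]
#' @export
input_spline <- function(knots, control_points, degree = 3L, lambda = 0,
                         log_scale = FALSE) {
  knots <- as.numeric(knots)
  control_points <- as.numeric(control_points)
  if (length(knots) < 2L) stop("need at least 2 knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  if (length(control_points) != length(knots))
    stop("number of control points must equal number of knots")
  if (degree != 3L) stop("only cubic splines (degree 3) are supported")
  if (lambda < 0) stop("lambda must be non-negative")
  structure(
    list(knots = knots, control_points = control_points, degree = 3L,
         lambda = lambda, log_scale = isTRUE(log_scale),
         m2 = natspline_m2(knots, control_points)),
    class = "input_spline")
}

#' @export
print.input_spline <- function(x, ...) {
  cat(sprintf(
    "<input_spline> %d knots on [%g, %g], lambda = %g, %s scale\n",
    length(x$knots), x$knots[1], x$knots[length(x$knots)], x$lambda,
    if (x$log_scale) "log10" else "linear"))
  invisible(x)
}

# Second derivatives M_1..M_N of the natural cubic interpolant of
# (knots, values); M_1 = M_N = 0.  Interior M solve R M = Q' v with the
# Green-Silverman band matrices.
natspline_m2 <- function(knots, values) {
  n <- length(knots)
  m2 <- numeric(n)
  if (n > 2L) {
    mats <- spline_matrices(knots)
    m2[2:(n - 1)] <- solve(mats$R, drop(crossprod(mats$Q, values)))
  }
  m2
}

# Band matrices of the curvature quadratic form of a natural cubic spline
# with values g at the knots: integral of S''(t)^2 over [t_1, t_N] equals
# g' K g with K = Q R^-1 Q' (Green & Silverman parametrization).
spline_matrices <- function(knots) {
  n <- length(knots)
  h <- diff(knots)
  ni <- n - 2L
  Q <- matrix(0, n, max(ni, 0L))
  R <- matrix(0, max(ni, 0L), max(ni, 0L))
  if (ni > 0L) {
    for (j in seq_len(ni)) {
      i <- j + 1L # interior knot index 2..n-1
      Q[i - 1L, j] <- 1 / h[i - 1L]
      Q[i, j] <- -1 / h[i - 1L] - 1 / h[i]
      Q[i + 1L, j] <- 1 / h[i]
      R[j, j] <- (h[i - 1L] + h[i]) / 3
      if (j < ni) R[j, j + 1L] <- R[j + 1L, j] <- h[i] / 6
    }
  }
  K <- if (ni > 0L) Q %*% solve(R, t(Q)) else matrix(0, n, n)
  list(Q = Q, R = R, K = K)
}

#' Natural cubic interpolation spline
#'
#' Returns the cubic spline with natural boundary conditions (zero curvature
#' at the first and last knot) that passes exactly through the given points.
#'
#' @param times strictly increasing vector of at least 2 time points.
#' @param values values to interpolate.
#' @param log_scale passed to [input_spline()].
#' @return An `input_spline` with `lambda = 0`.
#' @export
interpolating_spline <- function(times, values, log_scale = FALSE) {
  if (anyDuplicated(times)) stop("duplicate times are invalid")
  input_spline(times, values, lambda = 0, log_scale = log_scale)
}

#' Weighted cubic smoothing spline
#'
#' Minimizes
#' \deqn{\sum_i \left(\frac{S(t_i) - y_i}{\sigma_i}\right)^2 +
#'   \lambda \int_{t_1}^{t_N} S''(t)^2 \, dt}
#' over natural cubic splines.  `lambda = 0` reproduces the interpolation
#' spline; `lambda -> Inf` converges to the sigma-weighted straight-line
#' least-squares fit.  The minimizer is returned through its control points
#' `v_i = S(t_i)`, the canonical parametrization used by the joint estimator.
#'
#' The linear system is solved in the Reinsch form
#' `(R + lambda Q' W^-1 Q) gamma = Q' y`, which remains well conditioned for
#' very large `lambda`.
#'
#' @inheritParams interpolating_spline
#' @param sigmas positive per-point standard deviations.
#' @param lambda non-negative smoothing parameter.
#' @export
smoothing_spline <- function(times, values, sigmas, lambda,
                             log_scale = FALSE) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (any(sigmas <= 0)) stop("sigmas must be positive")
  n <- length(times)
  stopifnot(length(values) == n, length(sigmas) == n)
  if (n <= 2L || lambda == 0) {
    sp <- interpolating_spline(times, values, log_scale = log_scale)
    sp$lambda <- lambda
    return(sp)
  }
  mats <- spline_matrices(times)
  w_inv <- sigmas^2 # W^-1 for W = diag(1/sigma^2)
  A <- mats$R + lambda * crossprod(mats$Q, w_inv * mats$Q)
  lam_gamma <- lambda * solve(A, drop(crossprod(mats$Q, values)))
  g <- values - w_inv * drop(mats$Q %*% lam_gamma)
  input_spline(times, g, lambda = lambda, log_scale = log_scale)
}

#' Select the smoothing parameter by a chi-square discrepancy rule
#'
#' Returns the largest `lambda` on a log-spaced grid for which the weighted
#' residual sum of squares of the smoothing spline does not exceed the median
#' of the chi-square distribution with `N` degrees of freedom (`N` = number of
#' data points).  The rule smooths as strongly as the data permit while
#' keeping the fit statistically compatible with the measurement noise.
#'
#' @inheritParams smoothing_spline
#' @param grid candidate `lambda` values, tried in increasing order.
#' @param target residual bound; defaults to `qchisq(0.5, N)`.
#' @return The selected `lambda` (scalar).
#' @export
select_lambda <- function(times, values, sigmas,
                          grid = 10^seq(-6, 6, length.out = 25),
                          target = NULL) {
  n <- length(times)
  if (n < 4L) stop("need at least 4 points to select lambda")
  if (is.null(target)) target <- stats::qchisq(0.5, df = n)
  grid <- sort(grid)
  rss <- vapply(grid, function(l) {
    sp <- smoothing_spline(times, values, sigmas, l)
    sum(((sp$control_points - values) / sigmas)^2)
  }, numeric(1))
  ok <- which(rss <= target)
  if (length(ok) == 0L)
    stop("internal error: no grid lambda satisfies the chi-square bound; ",
         "extend the grid towards 0")
  grid[max(ok)]
}

#' Evaluate the spline curve S(t)
#'
#' @param spline an [input_spline()].
#' @param t time points.
#' @return `S(t)` on the spline's own (possibly log10) scale.
#' @export
evaluate_spline <- function(spline, t) {
  .natspline_eval_cpp(spline$knots, spline$control_points, spline$m2,
                      as.numeric(t))
}

#' Evaluate the input function u(t)
#'
#' For a log10-scale spline returns `10^S(t)` (strictly positive), otherwise
#' `S(t)`.  Also accepts the other input representations understood by
#' [simulate_model()] ([gaussian_input()], a plain function, a constant).
#'
#' @inheritParams evaluate_spline
#' @export
evaluate_input <- function(spline, t) {
  if (!inherits(spline, "input_spline"))
    return(evaluate_input_any(spline, t))
  s <- evaluate_spline(spline, t)
  if (spline$log_scale) 10^s else s
}

#' Integrated squared curvature of a spline
#'
#' Computes \eqn{\int_{t_1}^{t_N} S''(t)^2 dt} exactly: for a cubic spline
#' `S''` is piecewise linear, so the integral is the quadratic form
#' `v' K v` in the control points.
#'
#' @inheritParams evaluate_spline
#' @export
curvature_penalty <- function(spline) {
  v <- spline$control_points
  drop(v %*% spline_matrices(spline$knots)$K %*% v)
}

# Cholesky-type factor L' of K (K = L L', L' is (N-2) x N) such that the
# curvature penalty is ||L' v||^2.  Used to fold sqrt(lambda) * L' v into a
# least-squares residual vector.
penalty_factor <- function(knots) {
  n <- length(knots)
  if (n <= 2L) return(matrix(0, 0L, n))
  mats <- spline_matrices(knots)
  U <- chol(mats$R) # R = U'U
  # K = Q U^-1 U^-T Q'  =>  L' = U^-T Q'
  forwardsolve(t(U), t(mats$Q))
}

#' B-spline basis functions by the Cox-de Boor recursion
#'
#' Evaluates all degree-`p` B-spline basis functions on an extended
#' (e.g. clamped) knot vector at a time `t`.  On a clamped knot vector the
#' basis is a partition of unity, and an interpolating spline can be written
#' as a linear combination of these functions with the control points as
#' coefficients.
#'
#' @param knot_vector non-decreasing extended knot vector of length
#'   `n_basis + p + 1`.
#' @param degree polynomial degree `p >= 0`.
#' @param t scalar evaluation time inside the basis support
#'   `[knot_vector[p+1], knot_vector[n+1]]`.
#' @return Numeric vector of the `n_basis` basis values at `t`.
#' @export
bspline_basis <- function(knot_vector, degree, t) {
  p <- as.integer(degree)
  if (p < 0L) stop("degree must be >= 0")
  kv <- as.numeric(knot_vector)
  nb <- length(kv) - p - 1L
  if (nb < 1L) stop("knot vector too short for this degree")
  lo <- kv[p + 1L]
  hi <- kv[nb + 1L]
  if (t < lo || t > hi) stop("t outside the basis support")
  # degree 0: indicator of the knot interval (right-closed at the end)
  b <- numeric(length(kv) - 1L)
  j <- findInterval(t, kv, rightmost.closed = TRUE)
  j <- min(max(j, 1L), length(b))
  if (t >= hi) { # right endpoint: last non-degenerate interval
    j <- max(which(kv < hi))
  }
  b[j] <- 1
  if (p > 0L) {
    for (d in seq_len(p)) {
      nb_d <- length(kv) - d - 1L
      bn <- numeric(nb_d)
      for (i in seq_len(nb_d)) {
        den1 <- kv[i + d] - kv[i]
        den2 <- kv[i + d + 1L] - kv[i + 1L]
        w1 <- if (den1 > 0) (t - kv[i]) / den1 * b[i] else 0
        w2 <- if (den2 > 0) (kv[i + d + 1L] - t) / den2 * b[i + 1L] else 0
        bn[i] <- w1 + w2
      }
      b <- bn
    }
  }
  b[seq_len(nb)]
}

#' Clamped knot vector for a degree-p B-spline basis
#'
#' Repeats the boundary knots `p` additional times so the basis is clamped at
#' the data range.
#'
#' @param knots strictly increasing interior knot sequence `t_1..t_N`.
#' @param degree polynomial degree.
#' @export
clamped_knots <- function(knots, degree = 3L) {
  c(rep(knots[1], degree), knots, rep(knots[length(knots)], degree))
}

#' Serialize / deserialize a spline as JSON
#'
#' @param spline an [input_spline()].
#' @param path optional file; if `NULL` the JSON string is returned.
#' @export
spline_to_json <- function(spline, path = NULL) {
  rec <- list(knots = spline$knots, control_points = spline$control_points,
              degree = spline$degree, lambda = spline$lambda,
              log_scale = spline$log_scale)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname spline_to_json
#' @param json JSON string or path produced by [spline_to_json()].
#' @export
spline_from_json <- function(json) {
  rec <- jsonlite::fromJSON(json)
  input_spline(rec$knots, rec$control_points, degree = rec$degree,
               lambda = rec$lambda, log_scale = rec$log_scale)
}
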