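test_that("natural interpolation passes through the data with zero end curvature", {
  fx <- spline_fixture()
  sp <- interpolating_spline(fx$t, fx$y)

  expect_lt(max(abs(evaluate_spline(sp, fx$t) - fx$y)), 1e-10)

  # second derivative vanishes at the boundary knots (numerically)
  h <- 1e-4
  for (tb in c(fx$t[1], fx$t[length(fx$t)])) {
    tt <- pmin(pmax(c(tb - h, tb, tb + h), fx$t[1]), fx$t[length(fx$t)])
    # one-sided second difference just inside the interval
    t3 <- if (tb == fx$t[1]) tb + c(0, h, 2 * h) else tb - c(2 * h, h, 0)
    v <- evaluate_spline(sp, t3)
    expect_lt(abs((v[1] - 2 * v[2] + v[3]) / h^2), 1e-3)
  }

  # collinear data reproduce the straight line between knots
  lin <- interpolating_spline(c(0, 1, 2), c(0, 1, 2))
  expect_equal(evaluate_spline(lin, 0.5), 0.5, tolerance = 1e-12)

  expect_error(interpolating_spline(c(0, 1, 1), c(1, 2, 3)), "duplicate")
})

test_that("interpolation coefficients match a dense linear-algebra oracle", {
  set.seed(7)
  t <- sort(runif(5, 0, 10))
  y <- rnorm(5)
  sp <- interpolating_spline(t, y)

  # brute-force natural spline: solve the full tridiagonal system densely
  n <- 5; h <- diff(t)
  A <- matrix(0, n, n); b <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1] / 6
    A[i, i] <- (h[i - 1] + h[i]) / 3
    A[i, i + 1] <- h[i] / 6
    b[i] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
  }
  m2 <- solve(A, b)
  expect_equal(sp$m2, m2, tolerance = 1e-10)

  # and evaluation agrees with stats::spline natural interpolation
  tt <- seq(min(t), max(t), length.out = 37)
  ref <- stats::spline(t, y, xout = tt, method = "natural")$y
  expect_equal(evaluate_spline(sp, tt), ref, tolerance = 1e-9)
})

test_that("smoothing spline hits its two limits and is monotone in lambda", {
  fx <- spline_fixture()

  # lambda = 0: interpolation
  sp0 <- smoothing_spline(fx$t, fx$y, fx$s, lambda = 0)
  expect_equal(sp0$control_points, fx$y, tolerance = 1e-12)

  # lambda -> Inf: sigma-weighted straight-line fit
  spinf <- smoothing_spline(fx$t, fx$y, fx$s, lambda = 1e12)
  line <- weighted_line_fit(fx$t, fx$y, fx$s)
  expect_equal(spinf$control_points, line, tolerance = 1e-6)

  # data term non-decreasing, penalty non-increasing in lambda
  lams <- 10^seq(-4, 4, length.out = 15)
  fits <- lapply(lams, function(l)
    smoothing_spline(fx$t, fx$y, fx$s, lambda = l))
  rss <- vapply(fits, function(sp)
    sum(((sp$control_points - fx$y) / fx$s)^2), numeric(1))
  pen <- vapply(fits, curvature_penalty, numeric(1))
  expect_true(all(diff(rss) >= -1e-9))
  expect_true(all(diff(pen) <= 1e-9))

  expect_error(smoothing_spline(fx$t, fx$y, fx$s, lambda = -1))
})

test_that("curvature penalty is an exact quadratic form", {
  # collinear control points: zero curvature
  lin <- interpolating_spline(c(0, 2, 5, 9), c(1, 3, 6, 10))
  expect_lt(abs(curvature_penalty(lin)), 1e-12)

  # bump: agrees with adaptive quadrature of S''(t)^2
  sp <- interpolating_spline(0:6, c(0, 0.2, 1.5, 4, 1.5, 0.2, 0))
  d2 <- function(t) {
    h <- 1e-4
    (evaluate_spline(sp, t + h) - 2 * evaluate_spline(sp, t) +
       evaluate_spline(sp, t - h)) / h^2
  }
  quad <- sum(vapply(1:6, function(i)
    stats::integrate(function(t) d2(t)^2, i - 1 + 1e-3, i - 1e-3,
                     rel.tol = 1e-6)$value, numeric(1)))
  expect_equal(curvature_penalty(sp), quad, tolerance = 1e-2)

  # quadratic scaling in the control points
  sp3 <- interpolating_spline(0:6, 3 * c(0, 0.2, 1.5, 4, 1.5, 0.2, 0))
  expect_equal(curvature_penalty(sp3), 9 * curvature_penalty(sp),
               tolerance = 1e-10)

  # penalty pseudo-residual factor reproduces the quadratic form
  Lt <- jointinput:::penalty_factor(sp$knots)
  expect_equal(sum((Lt %*% sp$control_points)^2), curvature_penalty(sp),
               tolerance = 1e-10)
})

test_that("lambda selection follows the chi-square discrepancy rule", {
  # noise-free straight line: every lambda fits, grid maximum returned
  t <- seq(0, 10, length.out = 8)
  yl <- 2 + 0.5 * t
  grid <- 10^seq(-6, 6, length.out = 25)
  expect_equal(select_lambda(t, yl, rep(0.1, 8), grid = grid), max(grid))

  # noisy data: definitional check on the same grid
  fx <- spline_fixture()
  lam <- select_lambda(fx$t, fx$y, fx$s, grid = grid)
  bound <- qchisq(0.5, df = length(fx$t))
  rss_at <- function(l) {
    sp <- smoothing_spline(fx$t, fx$y, fx$s, l)
    sum(((sp$control_points - fx$y) / fx$s)^2)
  }
  expect_lte(rss_at(lam), bound)
  nxt <- grid[which(grid == lam) + 1]
  if (!is.na(nxt)) expect_gt(rss_at(nxt), bound)

  # doubling sigmas weakens the data constraint: selected lambda not smaller
  lam2 <- select_lambda(fx$t, fx$y, 2 * fx$s, grid = grid)
  expect_gte(lam2, lam)
})

test_that("log-scale evaluation is positive and constant splines stay flat", {
  sp <- input_spline(c(0, 1, 2, 3), c(-2, 3, -5, 1), log_scale = TRUE)
  tt <- seq(0, 3, length.out = 50)
  expect_true(all(evaluate_input(sp, tt) > 0))

  spc <- input_spline(c(0, 1, 2), rep(1.5, 3), log_scale = TRUE)
  expect_equal(evaluate_input(spc, c(0, 0.3, 2.9)), rep(10^1.5, 3),
               tolerance = 1e-12)

  # extrapolation: constant continuation at the boundary values
  fx <- spline_fixture()
  spx <- interpolating_spline(fx$t, fx$y)
  expect_equal(evaluate_spline(spx, -5), fx$y[1])
  expect_equal(evaluate_spline(spx, 60), fx$y[length(fx$y)])
})

test_that("B-spline basis satisfies the Cox-de Boor identities", {
  kn <- clamped_knots(0:5, 3)

  # degree 0 on plain knots: indicator of the containing interval
  b0 <- bspline_basis(0:5, 0, 2.5)
  expect_equal(b0, c(0, 0, 1, 0, 0))

  # partition of unity at interior points, any degree
  for (p in 0:3) {
    kv <- clamped_knots(0:5, p)
    for (t in c(0.3, 2.5, 4.99, 5)) {
      expect_equal(sum(bspline_basis(kv, p, t)), 1, tolerance = 1e-12)
    }
  }

  # cubic values match splines::splineDesign (independent recursion)
  tt <- c(0, 0.7, 2, 3.3, 5)
  ours <- t(vapply(tt, function(t) bspline_basis(kn, 3, t),
                   numeric(length(kn) - 4)))
  ref <- splines::splineDesign(kn, tt, ord = 4, outer.ok = FALSE)
  expect_equal(ours, unname(ref), tolerance = 1e-12)

  expect_error(bspline_basis(kn, 3, 7), "support")
})

test_that("spline JSON serialization round-trips", {
  fx <- spline_fixture()
  sp <- smoothing_spline(fx$t, fx$y, fx$s, lambda = 2.5, log_scale = TRUE)
  js <- spline_to_json(sp)
  sp2 <- spline_from_json(js)
  expect_equal(sp2$knots, sp$knots)
  expect_equal(sp2$control_points, sp$control_points)
  expect_equal(sp2$lambda, 2.5)
  expect_true(sp2$log_scale)
  expect_equal(evaluate_input(sp2, 17.3), evaluate_input(sp, 17.3))
})
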