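test_that("toy model right-hand side implements the mass-action scheme", {
  m <- toy_model()
  k <- c(k1 = 0.01, km1 = 1, k2 = 0.5, km2 = 0.1)

  # with u = 0 only the back-reaction k-1 * x2 feeds X1
  dx <- m$rhs(0, c(30, 20, 50), 0, k)
  expect_equal(dx[1], 20)

  # all rate constants zero: no reactions
  expect_equal(m$rhs(0, c(3, 7, 11), 5, k * 0), c(0, 0, 0))

  # closed interconversion chain conserves total mass for any state/input
  set.seed(1)
  for (i in 1:20) {
    x <- runif(3, 0, 100); u <- runif(1, 0, 100); kk <- runif(4, 0, 2)
    names(kk) <- names(k)
    expect_equal(sum(m$rhs(0, x, u, kk)), 0, tolerance = 1e-12)
  }
})

test_that("JAK-STAT right-hand side conserves total STAT5 in the flux balance", {
  m <- jakstat_model()
  p <- c(k1 = 2, k2 = 1.5, k3 = 0.3, k4 = 0.6, tau = 4)

  # resting state without input has zero derivative
  dx <- m$rhs(0, c(1, 0, 0, 0), 0, p, xlag = function(i) 0)
  expect_equal(dx, c(0, 0, 0, 0))

  # total STAT5 bookkeeping: x1 + x2 + 2 x3 + 2 x4 balances exactly once
  # the delayed outflow (which leaves x4 and enters x1) is counted on both
  # sides
  set.seed(2)
  for (i in 1:20) {
    x <- runif(4); u <- runif(1, 0, 3); xl <- runif(1)
    dx <- m$rhs(0, x, u, p, xlag = function(i) xl)
    expect_equal(dx[1] + dx[2] + 2 * dx[3] + 2 * dx[4], 0,
                 tolerance = 1e-12)
  }

  # observation map: phosphorylated sum (dimers count twice), cytoplasmic
  # total, input scaled
  y <- m$observe(c(0.4, 0.2, 0.1, 0.3), 2, c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(unname(y), c(0.2 + 2 * 0.1, 0.4 + 0.2 + 2 * 0.1, 2))
})

test_that("simulation conserves mass and freezes when all fluxes vanish", {
  d <- study_design()

  # all fluxes zero: constant trajectory
  p0 <- list(dynamic = c(k1 = 1, km1 = 0, k2 = 0, km2 = 0),
             initial = c(x1 = 30, x2 = 20, x3 = 50))
  # (u = 0 trips the log10 positivity floor in the input observable)
  w <- capture_warnings(simulate_model(toy_model(), p0, 0, c(0, 1)))
  expect_true(any(grepl("positivity floor", w)))
  tr0 <- suppressWarnings(
    simulate_model(toy_model(), p0, 0, seq(0, 50, length.out = 7)))
  expect_equal(tr0$x1, rep(30, 7), tolerance = 1e-9)
  expect_equal(tr0$x3, rep(50, 7), tolerance = 1e-9)

  # true study conditions: sum of states stays at 100
  tr <- true_trajectory(d)
  expect_equal(tr$x1 + tr$x2 + tr$x3, rep(100, nrow(tr)), tolerance = 1e-7)

  # observables are the log10 states / input
  expect_equal(tr$y2, log10(tr$x2), tolerance = 1e-12)
  expect_equal(tr$y4, log10(tr$u), tolerance = 1e-12)
})

test_that("compiled RK45 and lsoda agree, and halving tolerances self-converges", {
  d <- study_design()
  tt <- seq(0, 50, length.out = 31)
  a <- true_trajectory(d, times = tt, backend = "rk45",
                       rtol = 1e-8, atol = 1e-10)
  b <- true_trajectory(d, times = tt, backend = "desolve",
                       rtol = 1e-8, atol = 1e-10)
  expect_lt(max(abs(as.matrix(a[, 2:4]) - as.matrix(b[, 2:4]))), 1e-5)

  # self-convergence: tighter tolerances move the solution by less than
  # 10x the coarser tolerance (relative to state scale ~100)
  c1 <- true_trajectory(d, times = tt, rtol = 1e-6, atol = 1e-8)
  c2 <- true_trajectory(d, times = tt, rtol = 1e-9, atol = 1e-11)
  expect_lt(max(abs(as.matrix(c1[, 2:4]) - as.matrix(c2[, 2:4]))),
            10 * 1e-6 * 100)

  # determinism: identical calls give identical output
  a2 <- true_trajectory(d, times = tt, backend = "rk45",
                        rtol = 1e-8, atol = 1e-10)
  expect_identical(as.matrix(a[, 2:4]), as.matrix(a2[, 2:4]))
})

test_that("delay handling: tau = 0 reduces to a plain ODE and the chain converges to the delay solver", {
  m <- jakstat_model()
  tt <- seq(0, 60, length.out = 25)
  pEpoR <- gaussian_input(height = 1, centre = 10, width = 8)
  base <- list(dynamic = c(k1 = 2, k2 = 1.5, k3 = 0.3, k4 = 0.2, tau = 0),
               scaling_offset = c(s1 = 1, s2 = 1, s3 = 1),
               initial = c(STAT5 = 1, pSTAT5 = 0, pSTAT5_2 = 0,
                           npSTAT5_2 = 0))

  # tau = 0 through the delay machinery equals an independent delay-free RHS
  tr_tau0 <- simulate_model(m, base, pEpoR, tt)
  plain_rhs <- function(t, x, parms) {
    u <- evaluate_input(pEpoR, t)
    with(as.list(parms), {
      list(c(-k1 * u * x[1] + 2 * k4 * x[4],
             k1 * u * x[1] - 2 * k2 * x[2]^2,
             k2 * x[2]^2 - k3 * x[3],
             k3 * x[3] - k4 * x[4]))
    })
  }
  ref <- deSolve::lsoda(c(1, 0, 0, 0), tt, plain_rhs,
                        parms = base$dynamic[1:4], rtol = 1e-8,
                        atol = 1e-10)
  expect_lt(max(abs(as.matrix(tr_tau0[, 2:5]) - ref[, 2:5])), 1e-6)

  # linear chain approaches the direct delay-history solution as the chain
  # grows (fixed tau = 2)
  pd <- base; pd$dynamic["tau"] <- 2
  direct <- simulate_model(m, pd, pEpoR, tt, backend = "dede")
  err <- vapply(c(4L, 16L, 64L), function(mlen) {
    ch <- simulate_model(m, pd, pEpoR, tt, chain_length = mlen)
    max(abs(as.matrix(ch[, 2:5]) - as.matrix(direct[, 2:5])))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 5e-3)

  # total STAT5 is conserved in the delay-free system
  tot <- tr_tau0$STAT5 + tr_tau0$pSTAT5 + 2 * tr_tau0$pSTAT5_2 +
    2 * tr_tau0$npSTAT5_2
  expect_equal(tot, rep(1, length(tt)), tolerance = 1e-7)
})

test_that("evaluate_input on gaussian input matches its formula", {
  g <- gaussian_input(height = 100, centre = 25, width = 7.5)
  expect_equal(true_input(25), 100)
  expect_equal(jointinput:::evaluate_input_any(g, 25 + 7.5),
               100 * exp(-0.5), tolerance = 1e-12)
})

test_that("parameter sets keep block order, log scale and fixed mask", {
  ps <- parameter_set(dynamic = c(k1 = 0.01, km1 = 1),
                      initial = c(x1 = 30),
                      input_control = c(v1 = -0.4, v2 = 2),
                      fixed = "x1")
  expect_equal(ps$block,
               c("dynamic", "dynamic", "initial", "input_control",
                 "input_control"))
  expect_equal(ps$value[1], log10(0.01))
  expect_equal(ps$value[4], -0.4) # control points stored as is
  expect_equal(unname(ps_natural(ps, "dynamic")), c(0.01, 1))
  expect_true(ps$fixed[ps$name == "x1"])

  # free-value replacement never touches fixed entries
  ps2 <- jointinput:::ps_set_free(ps, c(9, 9, 9, 9))
  expect_equal(ps2$value[ps2$name == "x1"], log10(30))
})
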