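# Shared fixtures built in code.

# small noisy dataset on a smooth curve, fixed seed
spline_fixture <- function(n = 12, seed = 42) {
  set.seed(seed)
  t <- seq(0, 50, length.out = n)
  y <- log10(100 * exp(-0.5 * ((t - 25) / 7.5)^2) + 1) + rnorm(n, 0, 0.3)
  list(t = t, y = y, s = rep(0.3, n))
}

# quick toy-study objects reused across tests
toy_template <- function(design = study_design(), fixed = character(0)) {
  parameter_set(dynamic = design$dynamic, initial = design$initial,
                fixed = fixed)
}

# closed-form sigma-weighted straight-line fit
weighted_line_fit <- function(t, y, s) {
  w <- 1 / s^2
  X <- cbind(1, t)
  beta <- solve(crossprod(X, w * X), crossprod(X, w * y))
  drop(X %*% beta)
}
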