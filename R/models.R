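#' Construct an ODE model of a biochemical reaction network
#'
#' A model couples internal states `x(t)` governed by mass-action ODEs
#' `dx/dt = f(t, x, u, theta)` to a time-dependent external input `u(t)` and
#' to an observation map `y = g(x, u, s)`.  Observables are what the
#' estimator compares to data; one observable may be tagged as the direct
#' measurement of the input itself.
#'
#' @param name short model identifier.
#' @param state_names character vector of state identifiers.
#' @param rhs function `(t, x, u, p, xlag)` returning the derivative vector;
#'   `p` is the named dynamic-parameter vector (natural scale) and
#'   `xlag(i)` returns the value of state `i` at time `t - tau` for models
#'   with a discrete delay (zero history before the initial time).
#' @param observe function `(x, u, s)` returning the named observable
#'   vector; `s` holds scaling/offset parameters (natural scale).
#' @param observable_names names of the observables, in `observe()` order.
#' @param input_names names of the input functions (a single input is
#'   supported by the built-in solvers).
#' @param input_observable name of the observable that measures the input
#'   directly, or `NULL` if the input is unobserved.
#' @param dyn_names names of the dynamic parameters.
#' @param scale_names names of the scaling/offset parameters.
#' @param delay `NULL`, or `list(state = <index>, tau_name = <dynamic
#'   parameter holding the lag>)` for a single discrete delay term.
#' @param compiled internal flag: model has a compiled fast path.
#' @return An object of class `ode_model`.
#' @export
ode_model <- function(name, state_names, rhs, observe, observable_names,
                      input_names = "u", input_observable = NULL,
                      dyn_names, scale_names = character(0), delay = NULL,
                      compiled = FALSE) {
  structure(
    list(name = name, state_names = state_names, rhs = rhs,
         observe = observe, observable_names = observable_names,
         input_names = input_names, input_observable = input_observable,
         dyn_names = dyn_names, scale_names = scale_names, delay = delay,
         compiled = compiled),
    class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf("<ode_model> %s: %d states (%s), observables %s\n", x$name,
              length(x$state_names), paste(x$state_names, collapse = ", "),
              paste(x$observable_names, collapse = ", ")))
  if (!is.null(x$delay))
    cat(sprintf("  discrete delay on state %d (lag parameter %s)\n",
                x$delay$state, x$delay$tau_name))
  invisible(x)
}

# log10 with a positivity floor used only inside observation functions,
# never in the RHS.  Warns when the floor triggers.
log10_floor <- function(x, floor = 1e-12) {
  if (any(x < floor)) {
    warning("state/input below positivity floor 1e-12 inside log10 ",
            "observation; clipped", call. = FALSE)
    x <- pmax(x, floor)
  }
  log10(x)
}

#' The three-state illustrative model
#'
#' An interconversion chain `X1 <-> X2 <-> X3` in which the forward reaction
#' `X1 -> X2` is catalysed by the time-dependent input `u(t)`:
#' fluxes `v1 = k1 u x1`, `v-1 = k-1 x2`, `v2 = k2 x2`, `v-2 = k-2 x3`.
#' The system is closed, so the total mass `x1 + x2 + x3` is conserved along
#' every trajectory.  Observables are `y_i = log10(x_i)` for the three states
#' and `y4 = log10(u)` for the input, matching log-normally distributed
#' measurement noise of protein quantification assays.
#'
#' @return An [ode_model()].
#' @export
toy_model <- function() {
  ode_model(
    name = "toy",
    state_names = c("x1", "x2", "x3"),
    rhs = function(t, x, u, p, xlag = NULL) {
      v1 <- p[["k1"]] * u * x[1]
      vm1 <- p[["km1"]] * x[2]
      v2 <- p[["k2"]] * x[2]
      vm2 <- p[["km2"]] * x[3]
      c(-v1 + vm1, v1 - vm1 - v2 + vm2, v2 - vm2)
    },
    observe = function(x, u, s = NULL) {
      c(y1 = log10_floor(x[1]), y2 = log10_floor(x[2]),
        y3 = log10_floor(x[3]), y4 = log10_floor(u))
    },
    observable_names = c("y1", "y2", "y3", "y4"),
    input_names = "u",
    input_observable = "y4",
    dyn_names = c("k1", "km1", "k2", "km2"),
    compiled = TRUE)
}

#' The JAK2-STAT5 signalling model with transport delay
#'
#' Cytoplasmic STAT5 (`x1`) is phosphorylated at a rate proportional to the
#' phosphorylated Epo receptor input `u = pEpoR`; pSTAT5 (`x2`) dimerizes
#' (`x3 = pSTAT5_2`), the dimer is imported into the nucleus
#' (`x4 = npSTAT5_2`) and, after a residence delay `tau`, dissociates and
#' returns two unphosphorylated monomers to the cytoplasm:
#' \preformatted{
#'   dx1/dt = -k1 u x1 + 2 k4 x4(t - tau)
#'   dx2/dt =  k1 u x1 - 2 k2 x2^2
#'   dx3/dt =  k2 x2^2 - k3 x3
#'   dx4/dt =  k3 x3 - k4 x4(t - tau)
#' }
#' Total STAT5 `x1 + x2 + 2 x3 + 2 x4` is conserved once the delayed outflow
#' is included in the balance.  Immunoblotting observables are relative:
#' `y1 = s1 (x2 + 2 x3)` (phosphorylated STAT5), `y2 = s2 (x1 + x2 + 2 x3)`
#' (total cytoplasmic STAT5), `y3 = s3 u` (input measurement).  The
#' conventional identifiability fixings are `x1(0) = 1`,
#' `x2(0) = x3(0) = x4(0) = 0` and `s3 = 1`.
#'
#' @return An [ode_model()] with dynamic parameters `k1..k4, tau` and scaling
#'   parameters `s1..s3`.
#' @export
jakstat_model <- function() {
  ode_model(
    name = "jakstat",
    state_names = c("STAT5", "pSTAT5", "pSTAT5_2", "npSTAT5_2"),
    rhs = function(t, x, u, p, xlag) {
      x4d <- xlag(4L)
      phos <- p[["k1"]] * u * x[1]
      dim <- p[["k2"]] * x[2]^2
      imp <- p[["k3"]] * x[3]
      exp_ <- p[["k4"]] * x4d
      c(-phos + 2 * exp_, phos - 2 * dim, dim - imp, imp - exp_)
    },
    observe = function(x, u, s) {
      c(y1 = s[["s1"]] * (x[2] + 2 * x[3]),
        y2 = s[["s2"]] * (x[1] + x[2] + 2 * x[3]),
        y3 = s[["s3"]] * u)
    },
    observable_names = c("y1", "y2", "y3"),
    input_names = "pEpoR",
    input_observable = "y3",
    dyn_names = c("k1", "k2", "k3", "k4", "tau"),
    scale_names = c("s1", "s2", "s3"),
    delay = list(state = 4L, tau_name = "tau"))
}

#' Parameter sets
#'
#' A parameter set is a tibble with one row per parameter and a fixed block
#' order: dynamic rate constants, scaling/offset parameters, initial
#' concentrations, then input-spline control points.  Entries flagged `log10`
#' are stored on log10 scale (all analyses are carried out on log scale);
#' control points are already log10-input values and are stored as is.
#' `fixed` entries never move during optimization.
#'
#' @param dynamic,scaling_offset,initial named numeric vectors on natural
#'   scale (they are converted to log10 storage when flagged).
#' @param input_control spline control points (log10-input scale).
#' @param log10_blocks character vector of blocks stored on log10 scale.
#' @param fixed character vector of parameter names to hold fixed.
#' @return A tibble of class `parameter_set` with columns `name`, `block`,
#'   `value` (storage scale), `log10`, `fixed`.
#' @export
parameter_set <- function(dynamic, scaling_offset = numeric(0),
                          initial = numeric(0), input_control = numeric(0),
                          log10_blocks = c("dynamic", "scaling_offset",
                                           "initial"),
                          fixed = character(0)) {
  blk <- function(v, block) {
    if (length(v) == 0L) return(NULL)
    if (is.null(names(v)) && block == "input_control")
      names(v) <- paste0("v", seq_along(v))
    stopifnot(!is.null(names(v)))
    lg <- block %in% log10_blocks
    tibble::tibble(name = names(v), block = block,
                   value = if (lg) log10(unname(v)) else unname(v),
                   log10 = lg)
  }
  ps <- dplyr::bind_rows(blk(dynamic, "dynamic"),
                         blk(scaling_offset, "scaling_offset"),
                         blk(initial, "initial"),
                         blk(input_control, "input_control"))
  if (anyDuplicated(ps$name)) stop("duplicate parameter names")
  ps$fixed <- ps$name %in% fixed
  class(ps) <- c("parameter_set", class(ps))
  ps
}

#' Natural-scale values of one block of a parameter set
#'
#' @param params a [parameter_set()].
#' @param block one of `"dynamic"`, `"scaling_offset"`, `"initial"`,
#'   `"input_control"`.
#' @return Named numeric vector on natural scale (control points are
#'   returned on their storage scale, i.e. log10-input).
#' @export
ps_natural <- function(params, block) {
  rows <- params[params$block == block, ]
  v <- ifelse(rows$log10, 10^rows$value, rows$value)
  stats::setNames(v, rows$name)
}

# replace the storage-scale values of the free entries (used by optimizers)
ps_set_free <- function(params, free_values) {
  params$value[!params$fixed] <- free_values
  params
}

#' Simulate a model trajectory
#'
#' Integrates the ODE from the initial condition in `params` under the given
#' input function and returns states, input and observables at the requested
#' times as one wide tibble.
#'
#' Discrete delays are handled either by a linear chain of first-order
#' compartments appended to the state vector (`backend = "chain"`, default
#' length 8), so a standard stiff solver suffices, or by the direct
#' delay-differential solver (`backend = "dede"`).  Delayed states use zero
#' history before the initial time, consistent with initial values of zero.
#'
#' @param model an [ode_model()].
#' @param params a [parameter_set()] (or a plain list with elements
#'   `dynamic`, `scaling_offset`, `initial` on natural scale).
#' @param input the input function: an [input_spline()], a
#'   [gaussian_input()], a plain `function(t)`, or a constant.
#' @param times strictly increasing output times; integration starts at
#'   `times[1]`.
#' @param rtol,atol solver tolerances.
#' @param backend `"auto"` picks the compiled RK45 path for the built-in
#'   three-state model and `"desolve"` (lsoda, chain-expanded delays)
#'   otherwise.
#' @param chain_length number of compartments approximating a delay.
#' @return A tibble with columns `time`, the states, the input(s) and the
#'   observables.
#' @export
simulate_model <- function(model, params, input, times,
                           rtol = 1e-8, atol = 1e-10,
                           backend = c("auto", "rk45", "desolve", "dede"),
                           chain_length = 8L) {
  backend <- match.arg(backend)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (inherits(params, "parameter_set")) {
    p_dyn <- ps_natural(params, "dynamic")
    p_scale <- ps_natural(params, "scaling_offset")
    x0 <- ps_natural(params, "initial")
  } else {
    p_dyn <- params$dynamic
    p_scale <- params$scaling_offset
    x0 <- params$initial
  }
  if (length(x0) != length(model$state_names))
    stop("initial block must cover every state")

  if (backend == "auto")
    backend <- if (model$compiled && can_compile_input(input)) "rk45"
               else "desolve"

  if (backend == "rk45") {
    sol <- .rk45_toy(as.numeric(x0), as.numeric(times),
                     as.numeric(p_dyn[c("k1", "km1", "k2", "km2")]),
                     input_spec(input), rtol, atol)
    if (sol$status != 0)
      stop(sprintf("integration failed near t = %.4g", sol$tfail))
    states <- sol$states
    u_vals <- sol$u
  } else {
    u_fun <- function(t) evaluate_input_any(input, t)
    states <- integrate_desolve(model, x0, p_dyn, u_fun, times, rtol, atol,
                                backend, chain_length)
    u_vals <- vapply(times, u_fun, numeric(1))
  }
  colnames(states) <- model$state_names

  obs <- t(vapply(seq_along(times),
                  function(i) model$observe(states[i, ], u_vals[i], p_scale),
                  numeric(length(model$observable_names))))
  colnames(obs) <- model$observable_names

  out <- tibble::as_tibble(cbind(time = times, states))
  out[[model$input_names[1]]] <- u_vals
  dplyr::bind_cols(out, tibble::as_tibble(obs))
}

# deSolve integration with optional delay handling
integrate_desolve <- function(model, x0, p_dyn, u_fun, times, rtol, atol,
                              backend, chain_length) {
  n <- length(model$state_names)
  t0 <- times[1]
  has_delay <- !is.null(model$delay)
  tau <- if (has_delay) p_dyn[[model$delay$tau_name]] else 0

  if (!has_delay || tau == 0) {
    deriv <- function(t, x, parms) {
      xlag <- function(i) x[i]
      list(model$rhs(t, x, u_fun(t), p_dyn, xlag))
    }
    sol <- deSolve::lsoda(y = unname(x0), times = times, func = deriv,
                          parms = NULL, rtol = rtol, atol = atol)
    return(check_desolve(sol, times, n))
  }

  if (backend == "dede") {
    ds <- model$delay$state
    deriv <- function(t, x, parms) {
      xlag <- function(i) {
        if (t - tau <= t0) 0 else deSolve::lagvalue(t - tau, i)
      }
      list(model$rhs(t, x, u_fun(t), p_dyn, xlag))
    }
    sol <- deSolve::dede(y = unname(x0), times = times, func = deriv,
                         parms = NULL, rtol = rtol, atol = atol)
    return(check_desolve(sol, times, n))
  }

  # linear chain approximation: m first-order compartments with rate m/tau
  m <- as.integer(chain_length)
  ds <- model$delay$state
  rate <- m / tau
  deriv <- function(t, x, parms) {
    xs <- x[seq_len(n)]
    ch <- x[n + seq_len(m)]
    xlag <- function(i) {
      if (i == ds) ch[m] else xs[i]
    }
    dxs <- model$rhs(t, xs, u_fun(t), p_dyn, xlag)
    dch <- rate * (c(xs[ds], ch[-m]) - ch)
    list(c(dxs, dch))
  }
  y0 <- c(unname(x0), rep(0, m)) # zero history
  sol <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  check_desolve(sol, times, n)
}

check_desolve <- function(sol, times, n) {
  if (nrow(sol) < length(times))
    stop(sprintf("integration failed near t = %.4g", sol[nrow(sol), 1]))
  unname(as.matrix(sol[, 1 + seq_len(n), drop = FALSE]))
}

#' Gaussian-bell input function
#'
#' `u(t) = height * exp(-(t - centre)^2 / (2 width^2))`.
#'
#' @param height peak input value.
#' @param centre peak time.
#' @param width Gaussian width (same time units as `centre`).
#' @export
gaussian_input <- function(height = 100, centre = 25, width = 7.5) {
  structure(list(height = height, centre = centre, width = width),
            class = "gaussian_input")
}

# evaluate any supported input representation at scalar/vector t
evaluate_input_any <- function(input, t) {
  if (inherits(input, "input_spline")) return(evaluate_input(input, t))
  if (inherits(input, "gaussian_input"))
    return(input$height * exp(-0.5 * ((t - input$centre) / input$width)^2))
  if (is.function(input)) return(input(t))
  if (is.numeric(input) && length(input) == 1L) return(rep(input, length(t)))
  stop("unsupported input representation")
}

can_compile_input <- function(input) {
  inherits(input, "input_spline") || inherits(input, "gaussian_input")
}

# C++-side input descriptor
input_spec <- function(input) {
  if (inherits(input, "gaussian_input"))
    return(list(type = 0L, height = input$height, centre = input$centre,
                width = input$width))
  if (inherits(input, "input_spline"))
    return(list(type = if (input$log_scale) 1L else 2L,
                knots = input$knots, values = input$control_points,
                m2 = input$m2))
  stop("input cannot be passed to the compiled solver")
}
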