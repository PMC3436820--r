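#' Build a weighted least-squares objective
#'
#' Constructs the residual vector and scalar objective (twice the negative
#' log-likelihood up to a constant, for Gaussian noise) for one of the two
#' estimation approaches:
#'
#' * **standard** — the input is pre-fitted from the input data alone and
#'   frozen (`frozen_input`); only downstream observables contribute
#'   residuals and only dynamic/scaling/initial parameters are free.
#' * **comprehensive** — the input-spline control points are part of the
#'   parameter vector; residuals run over *all* observables including the
#'   input measurements, plus curvature pseudo-residuals
#'   `sqrt(lambda) L' v` so that `||residuals||^2` equals the data misfit
#'   plus `lambda` times the integrated squared curvature of the log10-input
#'   spline.
#'
#' Integration failures return a large sentinel residual vector
#' (`||r||^2 = 1e10`) and are counted in the objective's failure log.
#'
#' @param model an [ode_model()].
#' @param data measurement tibble with columns `time`, `observable`,
#'   `value`, `sigma`, `role`.
#' @param params a [parameter_set()] template fixing the layout, the fixed
#'   mask and the start values.  For the comprehensive approach it must
#'   contain an `input_control` block whose knots are the input measurement
#'   times.
#' @param approach `"standard"` or `"comprehensive"`.
#' @param frozen_input an [input_spline()]; required for the standard
#'   approach.
#' @param lambda curvature-penalty weight (comprehensive approach).
#' @param rtol,atol integration tolerances used inside the objective.
#' @param backend solver backend as in [simulate_model()].
#' @return An object of class `ls_objective`: a list with elements
#'   `residuals(free)`, `value(free)`, `params`, `free_names`, `n_residuals`
#'   and bookkeeping fields.
#' @export
make_objective <- function(model, data, params,
                           approach = c("comprehensive", "standard"),
                           frozen_input = NULL, lambda = 0,
                           rtol = 1e-7, atol = 1e-9,
                           backend = c("auto", "rk45", "desolve"),
                           sentinel = 1e10) {
  approach <- match.arg(approach)
  backend <- match.arg(backend)
  stopifnot(inherits(params, "parameter_set"))
  check_dataset(data, model)

  input_obs <- model$input_observable
  down <- data[data$role != "input", ]
  inp <- data[data$role == "input", ]
  if (approach == "standard") {
    if (is.null(frozen_input))
      stop("the standard approach requires a pre-fitted frozen_input spline")
    if (any(params$block == "input_control" & !params$fixed))
      stop("input control points must be fixed or absent in the standard approach")
  } else {
    if (!any(params$block == "input_control"))
      stop("comprehensive approach needs an input_control block in params")
    if (nrow(inp) == 0L)
      stop("comprehensive approach needs input-tagged observations")
  }

  times_out <- sort(unique(data$time))
  free <- !params$fixed
  free_names <- params$name[free]
  blocks <- params$block

  # residual bookkeeping for downstream observables
  d_row <- match(down$time, times_out)
  d_col <- match(down$observable, model$observable_names)
  d_val <- down$value
  d_sig <- down$sigma

  # comprehensive: spline machinery precomputed on the knot set
  if (approach == "comprehensive") {
    knots <- sort(unique(inp$time))
    v_names <- params$name[blocks == "input_control"]
    if (length(v_names) != length(knots))
      stop("number of input control points must equal number of input times")
    mats <- spline_matrices(knots)
    Uk <- if (length(knots) > 2L) chol(mats$R) else NULL
    Lt_pen <- penalty_factor(knots)
    # the spline interpolates its control points, so S(t) at an input
    # measurement time is the control point at that knot
    i_idx <- match(inp$time, knots)
    i_val <- inp$value
    i_sig <- inp$sigma
  }

  n_down <- nrow(down)
  n_inp <- if (approach == "comprehensive") nrow(inp) else 0L
  n_pen <- if (approach == "comprehensive" && lambda > 0)
    nrow(Lt_pen) else 0L
  n_res <- n_down + n_inp + n_pen

  failures <- new.env(parent = emptyenv())
  failures$n <- 0L

  use_rk45 <- model$compiled &&
    backend %in% c("auto", "rk45") &&
    length(model$scale_names) == 0L

  template <- params

  spline_m2 <- function(v) {
    if (is.null(Uk)) return(numeric(length(v)))
    m <- backsolve(Uk, backsolve(Uk, drop(crossprod(mats$Q, v)),
                                 transpose = TRUE))
    c(0, m, 0)
  }

  model_matrix <- function(p_full) {
    # returns list(obs matrix times_out x observables, ok flag)
    p_dyn <- ps_natural(p_full, "dynamic")
    p_scale <- ps_natural(p_full, "scaling_offset")
    x0 <- ps_natural(p_full, "initial")
    if (approach == "comprehensive") {
      v <- p_full$value[blocks == "input_control"]
      input <- list(type = 1L, knots = knots, values = v, m2 = spline_m2(v))
    } else {
      input <- frozen_input
    }
    if (use_rk45) {
      spec <- if (is.list(input) && !inherits(input, "input_spline"))
        input else input_spec(input)
      sol <- .rk45_toy(as.numeric(x0), times_out,
                       as.numeric(p_dyn[c("k1", "km1", "k2", "km2")]),
                       spec, rtol, atol)
      if (sol$status != 0) return(NULL)
      states <- sol$states
      u_vals <- sol$u
    } else {
      input_obj <- if (is.list(input) && !inherits(input, "input_spline")) {
        sp <- input_spline(input$knots, input$values, log_scale = TRUE)
        sp
      } else input
      u_fun <- function(t) evaluate_input_any(input_obj, t)
      states <- tryCatch(
        integrate_desolve(model, x0, p_dyn, u_fun, times_out, rtol, atol,
                          "desolve", 8L),
        error = function(e) NULL)
      if (is.null(states)) return(NULL)
      u_vals <- vapply(times_out, u_fun, numeric(1))
    }
    obs <- withCallingHandlers(
      t(vapply(seq_along(times_out),
               function(i) model$observe(states[i, ], u_vals[i], p_scale),
               numeric(length(model$observable_names)))),
      warning = function(w) invokeRestart("muffleWarning"))
    obs
  }

  residuals_fn <- function(free_values) {
    p_full <- ps_set_free(template, free_values)
    obs <- model_matrix(p_full)
    if (is.null(obs) || anyNA(obs)) {
      failures$n <- failures$n + 1L
      return(rep(sqrt(sentinel / n_res), n_res))
    }
    r <- (d_val - obs[cbind(d_row, d_col)]) / d_sig
    if (approach == "comprehensive") {
      v <- p_full$value[blocks == "input_control"]
      r <- c(r, (i_val - v[i_idx]) / i_sig)
      if (n_pen > 0L)
        r <- c(r, sqrt(lambda) * drop(Lt_pen %*% v))
    }
    r
  }

  structure(
    list(residuals = residuals_fn,
         value = function(free_values) sum(residuals_fn(free_values)^2),
         params = template, free_names = free_names,
         start = template$value[free],
         log10 = params$log10[free],
         n_residuals = n_res, approach = approach, lambda = lambda,
         model = model, data = data, frozen_input = frozen_input,
         failures = failures),
    class = "ls_objective")
}

check_dataset <- function(data, model = NULL) {
  need <- c("time", "observable", "value", "sigma", "role")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
  if (any(data$sigma <= 0)) stop("all sigma must be positive")
  if (!is.null(model)) {
    unknown <- setdiff(unique(data$observable), model$observable_names)
    if (length(unknown))
      stop("unknown observable(s): ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}
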