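#' Latin hypercube start points
#'
#' Draws `n_starts` stratified start vectors for multistart optimization:
#' each dimension is divided into `n_starts` equal bins and every bin
#' receives exactly one sample.
#'
#' @param n_starts number of start points.
#' @param lower,upper finite bounds per free parameter (log10 scale for
#'   log-flagged parameters).
#' @param seed integer seed; identical seeds give identical starts.
#' @return A `n_starts x d` matrix with one start per row.
#' @export
lhs_starts <- function(n_starts, lower, upper, seed = 1L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)))
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, d)
  sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
}

#' Fit a model to time-course data
#'
#' Maximum-likelihood estimation by bound-constrained Levenberg-Marquardt
#' least squares on log10-scale parameters, with optional Latin-hypercube
#' multistart.  Two approaches are supported:
#'
#' * `"standard"`: the input is pre-fitted on the input data alone (weighted
#'   smoothing spline; `lambda` selected by the chi-square rule when
#'   `lambda = "auto"`) and then frozen while the remaining parameters are
#'   fitted against the downstream data only.
#' * `"comprehensive"`: the input-spline control points are appended to the
#'   parameter vector and co-estimated against all data, with the curvature
#'   penalty `lambda` applied to the log10-input spline.  If `params` has no
#'   `input_control` block it is created automatically with knots at the
#'   input measurement times and start values equal to the measured input.
#'
#' @param data measurement tibble (`time`, `observable`, `value`, `sigma`,
#'   `role`).
#' @param model an [ode_model()].
#' @param params a [parameter_set()] with start values and the fixed mask.
#' @param approach `"comprehensive"` (default) or `"standard"`.
#' @param lambda curvature-penalty weight, or `"auto"` for the chi-square
#'   selection rule applied to the input data.
#' @param n_starts single start at `params` when 1; otherwise the number of
#'   Latin-hypercube starts within the bounds.
#' @param seed seed for the multistart sampler.
#' @param lower,upper box bounds on the free parameters (scalar or named
#'   vector, log10/storage scale).
#' @param rtol,atol integration tolerances inside the objective.
#' @param backend see [simulate_model()].
#' @param control list passed to [minpack.lm::nls.lm.control()] entries
#'   `maxiter`, `ftol`, `ptol`, `gtol`.
#' @param frozen_input optionally a pre-built [input_spline()] for the
#'   standard approach (otherwise fitted from the input data).
#' @return An object of class `input_fit`.
#' @examples
#' design <- study_design()
#' dat <- generate_realization(design, seed = 7)
#' tmpl <- parameter_set(dynamic = design$dynamic, initial = design$initial,
#'                       fixed = c("x1", "x2", "x3"))
#' fit <- fit_model(dat, toy_model(), tmpl, approach = "comprehensive",
#'                  lambda = 0)
#' tidy(fit)
#' @export
fit_model <- function(data, model, params,
                      approach = c("comprehensive", "standard"),
                      lambda = "auto", n_starts = 1L, seed = 1L,
                      lower = -5, upper = 5,
                      rtol = 1e-7, atol = 1e-9,
                      backend = c("auto", "rk45", "desolve"),
                      control = list(), frozen_input = NULL) {
  approach <- match.arg(approach)
  backend <- match.arg(backend)
  check_dataset(data, model)
  inp <- data[data$role == "input", ]

  lambda_val <- lambda
  if (identical(lambda, "auto")) {
    if (nrow(inp) < 4L) stop("lambda = 'auto' needs >= 4 input points")
    lambda_val <- select_lambda(inp$time, inp$value, inp$sigma)
  }

  if (approach == "standard" && is.null(frozen_input)) {
    if (nrow(inp) == 0L)
      stop("standard approach needs input observations (or frozen_input)")
    ord <- order(inp$time)
    frozen_input <- smoothing_spline(inp$time[ord], inp$value[ord],
                                     inp$sigma[ord], lambda_val,
                                     log_scale = TRUE)
  }

  if (approach == "comprehensive" &&
      !any(params$block == "input_control")) {
    ord <- order(inp$time)
    v0 <- stats::setNames(inp$value[ord], paste0("v", seq_len(nrow(inp))))
    params <- dplyr::bind_rows(
      params,
      tibble::tibble(name = names(v0), block = "input_control",
                     value = unname(v0), log10 = FALSE, fixed = FALSE))
    class(params) <- c("parameter_set", class(tibble::tibble()))
  }

  obj <- make_objective(model, data, params, approach = approach,
                        frozen_input = frozen_input,
                        lambda = if (approach == "comprehensive")
                          lambda_val else 0,
                        rtol = rtol, atol = atol, backend = backend)

  d <- length(obj$start)
  lo <- expand_bound(lower, obj$free_names)
  hi <- expand_bound(upper, obj$free_names)

  starts <- if (n_starts <= 1L) {
    matrix(pmin(pmax(obj$start, lo), hi), nrow = 1,
           dimnames = list(NULL, obj$free_names))
  } else {
    s <- lhs_starts(n_starts, lo, hi, seed = seed)
    colnames(s) <- obj$free_names
    s
  }

  ctrl <- utils::modifyList(
    list(maxiter = 300L, ftol = 1e-10, ptol = 1e-10, gtol = 1e-8), control)

  rows <- vector("list", nrow(starts))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], lower = lo, upper = hi, fn = obj$residuals,
        control = minpack.lm::nls.lm.control(
          maxiter = ctrl$maxiter, ftol = ctrl$ftol, ptol = ctrl$ptol,
          gtol = ctrl$gtol)),
      error = function(e) NULL)
    # info 1-4: convergence criteria met; 6-8: tolerances smaller than
    # machine-achievable improvement, i.e. converged to working precision;
    # 5: iteration cap hit (recorded, not used unless nothing else is)
    conv <- !is.null(res) && res$info %in% c(1:4, 6:8)
    val <- if (is.null(res)) Inf else res$deviance
    rows[[i]] <- tibble::tibble(start = i, seed = seed,
                                converged = conv, objective = val)
    keep <- conv || (is.null(best) || !best$conv)
    if (!is.null(res) && is.finite(val) && keep &&
        (is.null(best) || val < best$deviance || (conv && !best$conv))) {
      best <- res
      best$conv <- conv
    }
  }
  start_table <- dplyr::bind_rows(rows)
  if (is.null(best))
    stop("all optimization starts failed; start table:\n",
         paste(utils::capture.output(print(start_table)), collapse = "\n"))
  if (!best$conv)
    warning("no start met the convergence criteria; returning the best ",
            "iteration-capped result", call. = FALSE)

  estimate <- stats::setNames(coef(best), obj$free_names)
  fitted_params <- ps_set_free(obj$params, unname(estimate))

  structure(
    list(model = model, data = data, approach = approach,
         lambda = obj$lambda, frozen_input = frozen_input,
         params = fitted_params, estimate = estimate,
         objective = best$deviance, start_table = start_table,
         objective_fns = obj, lower = lo, upper = hi, control = ctrl,
         log10 = obj$log10, converged = best$conv),
    class = "input_fit")
}

expand_bound <- function(b, nm) {
  d <- length(nm)
  if (length(b) == 1L) return(stats::setNames(rep(b, d), nm))
  if (!is.null(names(b))) {
    out <- stats::setNames(rep(NA_real_, d), nm)
    out[names(b)] <- b
    if (anyNA(out)) stop("bounds must cover every free parameter")
    return(out)
  }
  stopifnot(length(b) == d)
  stats::setNames(b, nm)
}

#' Fitted input spline of a fit
#'
#' For a comprehensive fit, the spline through the fitted control points;
#' for a standard fit, the frozen pre-fitted spline.
#'
#' @param fit an [fit_model()] result.
#' @export
fitted_input <- function(fit) {
  if (fit$approach == "standard") return(fit$frozen_input)
  v <- fit$params$value[fit$params$block == "input_control"]
  inp <- fit$data[fit$data$role == "input", ]
  input_spline(sort(unique(inp$time)), v, lambda = fit$lambda,
               log_scale = TRUE)
}

#' @export
print.input_fit <- function(x, ...) {
  cat(sprintf(
    "<input_fit> %s approach, objective %.6g, %d/%d starts converged\n",
    x$approach, x$objective, sum(x$start_table$converged),
    nrow(x$start_table)))
  print(tidy(x))
  invisible(x)
}
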