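#' Profile likelihood of fitted parameters
#'
#' For each requested parameter the objective is re-minimized over all other
#' free parameters (including input control points in a comprehensive fit)
#' while the parameter is walked away from its maximum-likelihood estimate
#' in both directions with adaptive steps.  The walk stops when the profiled
#' objective exceeds `chi2_min + Delta_alpha` (with
#' `Delta_alpha = qchisq(alpha, df = 1)`, the point-wise likelihood-ratio
#' threshold) or when a parameter bound is reached.  A profile that reaches
#' a bound while still below the threshold marks the corresponding
#' confidence-interval end as open — the signature of practical
#' non-identifiability.
#'
#' @param fit an [fit_model()] result.
#' @param parameters names of free parameters to profile; default all
#'   non-control-point free parameters.
#' @param alpha confidence level defining the walk threshold (confidence
#'   intervals at any level up to `alpha` can then be read off the curves).
#' @param step list with `target_frac` (desired objective increase per step
#'   as a fraction of the threshold), `min_step`, `max_step` (log10 units)
#'   and `init` (initial step).
#' @param max_steps maximum walk length per direction.
#' @param control optimizer settings for the re-optimizations (defaults to
#'   the fit's own, with a smaller iteration cap).
#' @return An object of class `profile_set` with a `curves` tibble
#'   (`parameter`, `value`, `objective`, `converged`) and walk metadata.
#' @export
profile_fit <- function(fit, parameters = NULL, alpha = 0.95,
                        step = list(), max_steps = 200L, control = list()) {
  stopifnot(inherits(fit, "input_fit"))
  stp <- utils::modifyList(
    list(target_frac = 1 / 50, min_step = 1e-4, max_step = 0.5,
         init = 0.02), step)
  ctrl <- utils::modifyList(
    utils::modifyList(fit$control, list(maxiter = 100L)), control)

  free_names <- fit$objective_fns$free_names
  if (is.null(parameters)) {
    blocks <- fit$params$block[!fit$params$fixed]
    parameters <- free_names[blocks != "input_control"]
  }
  bad <- setdiff(parameters, free_names)
  if (length(bad))
    stop("not free parameters: ", paste(bad, collapse = ", "))

  delta <- stats::qchisq(alpha, df = 1)
  res_fn <- fit$objective_fns$residuals
  est <- fit$estimate
  obj_min <- fit$objective

  curves <- purrr::map_dfr(parameters, function(pn) {
    j <- match(pn, free_names)
    others <- setdiff(seq_along(est), j)
    lo_o <- fit$lower[others]
    hi_o <- fit$upper[others]

    reopt <- function(p_fix, start_others) {
      rfun <- function(q) {
        full <- numeric(length(est))
        full[others] <- q
        full[j] <- p_fix
        res_fn(full)
      }
      if (length(others) == 0L)
        return(list(value = sum(rfun(numeric(0))^2), par = numeric(0)))
      res <- tryCatch(
        minpack.lm::nls.lm(par = start_others, lower = lo_o, upper = hi_o,
                           fn = rfun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = ctrl$maxiter, ftol = ctrl$ftol,
                             ptol = ctrl$ptol, gtol = ctrl$gtol)),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      list(value = res$deviance, par = coef(res))
    }

    walk <- function(dir) {
      rows <- list()
      p_cur <- est[j]
      start_others <- est[others]
      h <- stp$init
      d_prev <- 0
      target <- delta * stp$target_frac
      n <- 0L
      while (n < max_steps) {
        n <- n + 1L
        p_next <- p_cur + dir * h
        at_bound <- FALSE
        if (dir > 0 && p_next >= fit$upper[j]) {
          p_next <- fit$upper[j]; at_bound <- TRUE
        }
        if (dir < 0 && p_next <= fit$lower[j]) {
          p_next <- fit$lower[j]; at_bound <- TRUE
        }
        opt <- reopt(p_next, start_others)
        if (is.null(opt)) {
          # re-optimization failure: flag the point, shrink the step
          rows[[length(rows) + 1L]] <-
            tibble::tibble(value = p_next, objective = NA_real_,
                           converged = FALSE)
          h <- max(stp$min_step, h / 2)
          if (at_bound) break
          next
        }
        rows[[length(rows) + 1L]] <-
          tibble::tibble(value = p_next, objective = opt$value,
                         converged = TRUE)
        d_cur <- opt$value - obj_min
        if (d_cur > delta * 1.001 || at_bound) break
        gain <- d_cur - d_prev
        fac <- if (gain <= 0) 2 else max(0.5, min(2, target / gain))
        h <- min(stp$max_step, max(stp$min_step, h * fac))
        d_prev <- d_cur
        p_cur <- p_next
        start_others <- opt$par
      }
      dplyr::bind_rows(rows)
    }

    up <- walk(+1)
    down <- walk(-1)
    dplyr::bind_rows(
      down[rev(seq_len(nrow(down))), ],
      tibble::tibble(value = est[j], objective = obj_min, converged = TRUE),
      up) |>
      dplyr::mutate(parameter = pn, .before = 1)
  })

  structure(
    list(curves = curves, obj_min = obj_min, estimate = est,
         lower = fit$lower, upper = fit$upper,
         log10 = stats::setNames(fit$log10, free_names),
         alpha_walk = alpha, approach = fit$approach),
    class = "profile_set")
}

#' Likelihood-based confidence intervals from profiles
#'
#' Reads the threshold crossings of each profile curve by monotone linear
#' interpolation between adjacent grid points.  A profile that reaches its
#' parameter bound while still below the threshold yields an open interval
#' end (`0` on the lower, `Inf` on the upper natural-scale side for
#' log10-scale parameters).  A side on which the walk stopped without
#' crossing and without reaching a bound is flagged as not determined
#' (`NA`).
#'
#' @param profiles a [profile_fit()] result.
#' @param alpha confidence level; must not exceed the level the walk was
#'   computed for.
#' @return A tibble with columns `parameter`, `estimate`, `lower`, `upper`
#'   (storage/log10 scale; `-Inf`/`Inf` for open ends), `conf_lb`,
#'   `conf_ub` (natural scale), `open_lower`, `open_upper`, `alpha`.
#' @export
confidence_interval <- function(profiles, alpha = 0.95) {
  stopifnot(inherits(profiles, "profile_set"))
  if (alpha > profiles$alpha_walk + 1e-12)
    stop("profiles were walked only to alpha = ", profiles$alpha_walk)
  delta <- stats::qchisq(alpha, df = 1)
  # re-anchor at the profile minimum: a walk that dips below the fitted
  # optimum has found a better optimum, and the likelihood-ratio threshold
  # is relative to the best value seen
  obj_min <- min(profiles$obj_min,
                 min(profiles$curves$objective, na.rm = TRUE))
  thr <- obj_min + delta

  one <- function(cv, pn) {
    cv <- cv[!is.na(cv$objective), ]
    est <- profiles$estimate[[pn]]
    i0 <- which.min(abs(cv$value - est))

    side <- function(idx, bound, dir) {
      # idx: indices walking outward from the estimate
      vals <- cv$value[idx]
      objs <- cv$objective[idx]
      cross <- which(objs > thr)
      if (length(cross)) {
        ic <- cross[1]
        if (ic == 1L) return(list(x = vals[1], open = FALSE))
        return(list(x = cross_interp(vals, objs, ic, thr), open = FALSE))
      }
      if (length(vals) && abs(vals[length(vals)] - bound) < 1e-9)
        return(list(x = if (dir > 0) Inf else -Inf, open = TRUE))
      list(x = NA_real_, open = FALSE) # not determined
    }

    upr <- side(seq(i0, nrow(cv)), profiles$upper[[pn]], +1)
    lwr <- side(rev(seq(1, i0)), profiles$lower[[pn]], -1)
    is_log <- isTRUE(profiles$log10[[pn]])
    nat <- function(x) if (is_log) 10^x else x
    tibble::tibble(
      parameter = pn, estimate = est,
      lower = lwr$x, upper = upr$x,
      conf_lb = nat(lwr$x), conf_ub = nat(upr$x),
      open_lower = lwr$open, open_upper = upr$open, alpha = alpha)
  }

  purrr::map_dfr(unique(profiles$curves$parameter), function(pn) {
    one(profiles$curves[profiles$curves$parameter == pn, ], pn)
  })
}

# Threshold crossing between grid points ic-1 and ic.  A quadratic through
# the last three points is used where available (exact for locally
# parabolic profiles, removing the systematic inward bias of a linear
# chord on a convex profile); falls back to linear interpolation.
cross_interp <- function(vals, objs, ic, thr) {
  x0 <- vals[ic - 1L]; x1 <- vals[ic]
  y0 <- objs[ic - 1L]; y1 <- objs[ic]
  lin <- x0 + (thr - y0) / (y1 - y0) * (x1 - x0)
  if (ic < 3L) return(lin)
  xs <- vals[(ic - 2L):ic]; ys <- objs[(ic - 2L):ic]
  co <- tryCatch(solve(cbind(1, xs, xs^2), ys), error = function(e) NULL)
  if (is.null(co) || abs(co[3]) < 1e-12) return(lin)
  disc <- co[2]^2 - 4 * co[3] * (co[1] - thr)
  if (disc < 0) return(lin)
  roots <- (-co[2] + c(-1, 1) * sqrt(disc)) / (2 * co[3])
  inside <- roots[roots >= min(x0, x1) - 1e-12 &
                  roots <= max(x0, x1) + 1e-12]
  if (length(inside) == 1L) return(inside)
  lin
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %d parameter(s), walked to alpha = %g\n",
              length(unique(x$curves$parameter)), x$alpha_walk))
  print(confidence_interval(x, x$alpha_walk))
  invisible(x)
}
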