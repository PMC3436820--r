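#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fit against its data
#'
#' Model observable trajectories (dense grid) overlaid on the measurements
#' with error bars, one facet per observable.
#'
#' @param object an [fit_model()] result.
#' @param n_grid number of plotting time points.
#' @param ... unused.
#' @export
autoplot.input_fit <- function(object, n_grid = 200L, ...) {
  dat <- object$data
  tg <- seq(min(dat$time), max(dat$time), length.out = n_grid)
  traj <- simulate_model(object$model, object$params,
                         fitted_input(object), tg)
  long <- tidyr::pivot_longer(
    traj[, c("time", object$model$observable_names)],
    -"time", names_to = "observable", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(data = long, colour = "steelblue") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$value - .data$sigma,
                   ymax = .data$value + .data$sigma), size = 0.2) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time", y = "observable",
                  title = sprintf("%s fit (objective %.3g)",
                                  object$approach, object$objective))
}

#' Plot profile-likelihood curves
#'
#' One facet per profiled parameter, with the confidence threshold as a
#' dashed line.
#'
#' @param object a [profile_fit()] result.
#' @param alpha level for the threshold line.
#' @param ... unused.
#' @export
autoplot.profile_set <- function(object, alpha = object$alpha_walk, ...) {
  thr <- object$obj_min + stats::qchisq(alpha, df = 1)
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$value, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "parameter value (log10)", y = "objective",
                  title = sprintf("profile likelihood (alpha = %g)", alpha))
}

#' Plot a Monte-Carlo summary
#'
#' @param object an [run_study()] result.
#' @param type `"estimates"` (densities of the estimates by approach),
#'   `"coverage"` (coverage ratio vs confidence level, with the identity as
#'   dashed line) or `"scores"` (score distributions).
#' @param ... unused.
#' @export
autoplot.mc_summary <- function(object,
                                type = c("estimates", "coverage",
                                         "scores"), ...) {
  type <- match.arg(type)
  if (type == "estimates") {
    truth_df <- tibble::tibble(parameter = names(object$truth),
                               truth = unname(object$truth))
    ggplot2::ggplot(object$estimates,
                    ggplot2::aes(x = .data$estimate,
                                 colour = .data$approach)) +
      ggplot2::geom_density() +
      ggplot2::geom_vline(data = truth_df,
                          ggplot2::aes(xintercept = .data$truth),
                          linetype = "dashed") +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = "estimate (log10)", y = "density")
  } else if (type == "coverage") {
    cov <- coverage(object$ci, object$truth)
    ggplot2::ggplot(cov, ggplot2::aes(x = .data$alpha, y = .data$coverage,
                                      colour = .data$approach)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_abline(linetype = "dashed") +
      ggplot2::facet_wrap(~parameter) +
      ggplot2::labs(x = "confidence level", y = "coverage ratio")
  } else {
    ggplot2::ggplot(object$scores,
                    ggplot2::aes(x = .data$score,
                                 colour = .data$approach)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~observable, scales = "free") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "trajectory score", y = "density")
  }
}
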