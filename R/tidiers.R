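#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fit into a parameter table
#'
#' @param x an [fit_model()] result.
#' @param ... unused.
#' @return Tibble with `parameter`, `block`, `estimate_log10` (storage
#'   scale) and `estimate` (natural scale), free parameters only.
#' @export
tidy.input_fit <- function(x, ...) {
  p <- x$params[!x$params$fixed, ]
  tibble::tibble(
    parameter = p$name, block = p$block,
    estimate_log10 = ifelse(p$log10, p$value, NA_real_),
    estimate = ifelse(p$log10, 10^p$value, p$value))
}

#' @rdname tidy.input_fit
#' @export
glance.input_fit <- function(x, ...) {
  tibble::tibble(
    approach = x$approach, objective = x$objective, lambda = x$lambda,
    n_starts = nrow(x$start_table),
    n_converged = sum(x$start_table$converged),
    n_free = length(x$estimate),
    integration_failures = x$objective_fns$failures$n)
}

#' Tidy profile curves into a confidence-interval table
#'
#' @param x a [profile_fit()] result.
#' @param alpha confidence level.
#' @param ... unused.
#' @export
tidy.profile_set <- function(x, alpha = x$alpha_walk, ...) {
  confidence_interval(x, alpha)
}

#' Tidy a Monte-Carlo summary
#'
#' @param x an [run_study()] result.
#' @param type `"precision"` (per-parameter accuracy, precision and
#'   standard/comprehensive precision ratio), `"coverage"`, or `"scores"`
#'   (per-observable median scores by approach).
#' @param ... unused.
#' @export
tidy.mc_summary <- function(x, type = c("precision", "coverage", "scores"),
                            ...) {
  type <- match.arg(type)
  if (type == "precision") {
    acc <- accuracy(x$estimates, x$truth)
    prec <- precision(x$estimates)
    wide <- precision_ratio(x)
    dplyr::left_join(
      tidyr::pivot_wider(acc, names_from = "approach",
                         values_from = "accuracy",
                         names_prefix = "accuracy_"),
      dplyr::rename(wide, precision_standard = "standard",
                    precision_comprehensive = "comprehensive"),
      by = "parameter")
  } else if (type == "coverage") {
    if (is.null(x$ci)) stop("study was run without profiles")
    coverage(x$ci, x$truth)
  } else {
    x$scores |>
      dplyr::summarise(median_score = stats::median(.data$score),
                       .by = c("approach", "observable"))
  }
}

#' @rdname tidy.mc_summary
#' @export
glance.mc_summary <- function(x, ...) {
  tibble::tibble(M = x$M, n_ok = length(unique(x$estimates$realization)),
                 n_excluded = length(x$excluded), seed = x$seed,
                 sigma_x = x$design$sigma_x, sigma_u = x$design$sigma_u)
}
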