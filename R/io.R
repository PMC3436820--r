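#' Read a measurement table
#'
#' Reads a TSV/CSV file with columns `time`, `observable`, `value`, `sigma`
#' into a typed measurement tibble, validates it against a model, and tags
#' each record as `downstream` or `input` according to the model's input
#' observable.
#'
#' @param path file path (tab- or comma-separated, with header).
#' @param model an [ode_model()] used for validation and role tagging.
#' @return Measurement tibble with columns `time`, `observable`, `value`,
#'   `sigma`, `role`.
#' @export
read_dataset <- function(path, model) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  need <- c("time", "observable", "value", "sigma")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("time", "value", "sigma")) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !is.na(raw[[cc]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' on line %d", cc, bad[1] + 1L))
    if (anyNA(v))
      stop(sprintf("missing '%s' on line %d", cc, which(is.na(v))[1] + 1L))
    raw[[cc]] <- v
  }
  bad_sigma <- which(raw$sigma <= 0)
  if (length(bad_sigma))
    stop(sprintf("non-positive sigma on line %d", bad_sigma[1] + 1L))
  unknown <- which(!raw$observable %in% model$observable_names)
  if (length(unknown))
    stop(sprintf("unknown observable '%s' on line %d",
                 raw$observable[unknown[1]], unknown[1] + 1L))
  raw$role <- ifelse(raw$observable %in% model$input_observable,
                     "input", "downstream")
  tibble::as_tibble(raw[, c(need, "role")])
}

#' Write a measurement table
#'
#' @param data measurement tibble.
#' @param path output TSV path.
#' @export
write_dataset <- function(data, path) {
  readr::write_tsv(data[, c("time", "observable", "value", "sigma")], path)
  invisible(path)
}

#' Write results to JSON (machine) and TSV (human) files
#'
#' Dispatches on the result type: an [fit_model()] result yields a JSON
#' record (parameter names, estimates on log10 and natural scale, objective,
#' start table, configuration fingerprint) plus a TSV parameter table; a
#' [profile_fit()] result yields the per-parameter curves and a
#' Table-style CI summary (`parameter`, `estimate`, `conf_lb`, `conf_ub`,
#' with `inf` marking open ends); an [run_study()] summary yields its
#' pooled tables.
#'
#' @param x result object.
#' @param path output path; the TSV companion replaces the extension.
#' @param ... further arguments (e.g. `alpha` for profiles).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

tsv_companion <- function(path) sub("\\.json$", ".tsv", path)

fingerprint <- function(x) rlang::hash(x)

#' @export
write_results.input_fit <- function(x, path, ...) {
  td <- tidy(x)
  rec <- list(
    approach = x$approach, lambda = x$lambda, objective = x$objective,
    parameters = td,
    start_table = x$start_table,
    fingerprint = fingerprint(list(x$approach, x$lambda, x$control,
                                   x$lower, x$upper, x$data)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  tsv <- tsv_companion(path)
  readr::write_tsv(td, tsv)
  invisible(c(path, tsv))
}

#' @export
write_results.profile_set <- function(x, path, alpha = x$alpha_walk, ...) {
  ci <- confidence_interval(x, alpha)
  rec <- list(alpha = alpha, curves = x$curves, ci = ci)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  tsv <- tsv_companion(path)
  out <- ci[, c("parameter", "estimate", "conf_lb", "conf_ub")]
  out$estimate <- signif(ifelse(x$log10[out$parameter],
                                10^out$estimate, out$estimate), 3)
  out$conf_lb <- ifelse(is.infinite(ci$conf_lb) | ci$open_lower, "0",
                        as.character(signif(out$conf_lb, 3)))
  out$conf_ub <- ifelse(is.infinite(ci$conf_ub) | ci$open_upper, "inf",
                        as.character(signif(as.numeric(out$conf_ub), 3)))
  readr::write_tsv(out, tsv)
  invisible(c(path, tsv))
}

#' @export
write_results.mc_summary <- function(x, path, ...) {
  rec <- list(M = x$M, seed = x$seed, excluded = x$excluded,
              truth_log10 = as.list(x$truth),
              estimates = x$estimates, scores = x$scores)
  if (!is.null(x$ci)) {
    rec$coverage <- coverage(x$ci, x$truth)
    rec$ci <- x$ci
  }
  rec$precision <- tidy(x)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  tsv <- tsv_companion(path)
  readr::write_tsv(tidy(x), tsv)
  invisible(c(path, tsv))
}

#' Load a model from a declarative YAML/JSON config
#'
#' The config lists state names, right-hand-side expressions (one arithmetic
#' expression per state over states, inputs and parameters), observation
#' expressions, and parameter declarations with roles.  Example:
#' \preformatted{
#' name: toy
#' states: [x1, x2, x3]
#' input: u
#' input_observable: y4
#' parameters:
#'   dynamic: [k1, km1, k2, km2]
#' rhs:
#'   x1: -k1 * u * x1 + km1 * x2
#'   x2:  k1 * u * x1 - km1 * x2 - k2 * x2 + km2 * x3
#'   x3:  k2 * x2 - km2 * x3
#' observations:
#'   y1: log10(x1)
#'   y2: log10(x2)
#'   y3: log10(x3)
#'   y4: log10(u)
#' }
#'
#' @param path YAML (or JSON) model description.
#' @return An [ode_model()].
#' @export
model_from_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
         else yaml::read_yaml(path)
  states <- cfg$states
  input <- cfg$input %||% "u"
  dyn <- cfg$parameters$dynamic
  scl <- cfg$parameters$scaling_offset %||% character(0)
  rhs_exprs <- lapply(cfg$rhs[states], function(s) parse(text = s)[[1]])
  obs_exprs <- lapply(cfg$observations, function(s) parse(text = s)[[1]])

  rhs <- function(t, x, u, p, xlag = NULL) {
    env <- c(as.list(stats::setNames(x, states)),
             as.list(p), stats::setNames(list(u), input), list(t = t))
    vapply(rhs_exprs, eval, numeric(1), envir = list2env(env))
  }
  observe <- function(x, u, s = NULL) {
    env <- c(as.list(stats::setNames(x, states)), as.list(s),
             stats::setNames(list(u), input))
    vapply(obs_exprs, eval, numeric(1), envir = list2env(env))
  }
  ode_model(name = cfg$name %||% "config", state_names = states,
            rhs = rhs, observe = observe,
            observable_names = names(cfg$observations),
            input_names = input,
            input_observable = cfg$input_observable,
            dyn_names = dyn, scale_names = scl)
}

#' Retrieve a built-in model by name
#'
#' @param name `"toy"`, `"jakstat"`, or a path to a model config file.
#' @export
get_model <- function(name) {
  switch(name,
         toy = toy_model(),
         jakstat = jakstat_model(),
         {
           if (!file.exists(name)) stop("unknown model: ", name)
           model_from_config(name)
         })
}
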