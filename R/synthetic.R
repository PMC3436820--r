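#' Simulation study design for the illustrative model
#'
#' Encodes the ground truth of the simulation study on the three-state
#' model: true rate constants `k1 = 0.01, k-1 = 1, k2 = 0.5, k-2 = 0.1`,
#' initial concentrations `(30, 20, 50)` (close to the steady state, which
#' maximizes the impact of the input), `N = 12` equidistant sampling times on
#' `[0, 50]`, a Gaussian-bell input peaking at `u(25) = 100`, and additive
#' Gaussian noise on the log10 observables with `sigma_x = 0.1` for the
#' states and `sigma_u = 0.3` for the input (log-normal noise on natural
#' scale).
#'
#' @param t0,t_end observation window.
#' @param n_times number of equidistant sampling times (endpoints included).
#' @param dynamic true rate constants (natural scale).
#' @param initial true initial concentrations.
#' @param input_height,input_centre,input_width Gaussian-bell input shape.
#' @param sigma_x,sigma_u noise standard deviations on the log10 observation
#'   scale for states and input.
#' @return An object of class `study_design`.
#' @export
study_design <- function(t0 = 0, t_end = 50, n_times = 12L,
                         dynamic = c(k1 = 0.01, km1 = 1, k2 = 0.5,
                                     km2 = 0.1),
                         initial = c(x1 = 30, x2 = 20, x3 = 50),
                         input_height = 100, input_centre = 25,
                         input_width = 7.5,
                         sigma_x = 0.1, sigma_u = 0.3) {
  stopifnot(t_end > t0, n_times >= 2L, sigma_x >= 0, sigma_u >= 0,
            input_centre >= t0, input_centre <= t_end)
  structure(
    list(t0 = t0, t_end = t_end, n_times = as.integer(n_times),
         times = seq(t0, t_end, length.out = n_times),
         dynamic = dynamic, initial = initial,
         input = gaussian_input(input_height, input_centre, input_width),
         sigma_x = sigma_x, sigma_u = sigma_u),
    class = "study_design")
}

#' True input of the simulation study
#'
#' The Gaussian bell `u(t) = 100 exp(-(t - 25)^2 / (2 w^2))` with its maximum
#' of 100 at `t = 25` (defaults of [study_design()]).
#'
#' @param t time points.
#' @param design a [study_design()].
#' @export
true_input <- function(t, design = study_design()) {
  evaluate_input_any(design$input, t)
}

#' Noise-free trajectory of the study design
#'
#' @param design a [study_design()].
#' @param times output times; defaults to the design sampling times.
#' @param ... passed to [simulate_model()].
#' @return The [simulate_model()] tibble at the true parameters.
#' @export
true_trajectory <- function(design, times = design$times, ...) {
  simulate_model(toy_model(),
                 list(dynamic = design$dynamic, initial = design$initial),
                 design$input, times, ...)
}

#' Generate one noisy dataset of the simulation study
#'
#' Simulates the three-state model at the true parameters, samples the four
#' observables `y1..y3 = log10(x_i)` and `y4 = log10(u)` at the design
#' times, and adds independent Gaussian noise (`sigma_x` for states,
#' `sigma_u` for the input) on the log10 scale.  The noise standard
#' deviation used is attached as the per-record `sigma`; when a noise level
#' is zero the record is reported with unit sigma so weighted least squares
#' stays defined.
#'
#' @param design a [study_design()].
#' @param seed integer seed; identical seeds reproduce the dataset exactly.
#' @param truth optional pre-computed [true_trajectory()] at the design
#'   times, to amortize the ODE solve across many realizations.
#' @return A measurement tibble with columns `time`, `observable`, `value`,
#'   `sigma`, `role` (`"downstream"` or `"input"`).
#' @export
generate_realization <- function(design, seed, truth = NULL) {
  if (is.null(truth)) truth <- true_trajectory(design)
  stopifnot(nrow(truth) == design$n_times)
  states <- as.matrix(truth[, c("x1", "x2", "x3")])
  if (any(states <= 0)) {
    bad <- which(states <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive state at sampling time t = %g; cannot take log10",
                 truth$time[bad[1]]))
  }
  u <- truth$u
  if (any(u <= 0)) stop("non-positive input at a sampling time")

  set.seed(seed)
  n <- design$n_times
  rep_sigma <- function(s) if (s > 0) s else 1
  recs <- list()
  for (i in 1:3) {
    recs[[i]] <- tibble::tibble(
      time = truth$time, observable = paste0("y", i),
      value = log10(states[, i]) + stats::rnorm(n, 0, design$sigma_x),
      sigma = rep_sigma(design$sigma_x), role = "downstream")
  }
  recs[[4]] <- tibble::tibble(
    time = truth$time, observable = "y4",
    value = log10(u) + stats::rnorm(n, 0, design$sigma_u),
    sigma = rep_sigma(design$sigma_u), role = "input")
  dplyr::bind_rows(recs)
}
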