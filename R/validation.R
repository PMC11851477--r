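# Known-circuit validation bench: a single-resistor RLC system with known
# parameters, the parameter-recovery experiment that exercises the optimizer
# on it, and the synthetic fixture generator for fitting tests.

#' Build the known-parameter validation system
#'
#' A series inertance L feeding a parallel R-C pair, with states capacitor
#' voltage `v` and inductor current `i`, source voltage `vs` as input and the
#' resistor current `ix = v/R` as output:
#' \deqn{A = \begin{pmatrix} -1/(RC) & 1/C \\ -1/L & 0 \end{pmatrix}, \quad
#'       B = (0, 1/L)^T, \quad Cout = (1/R, 0), \quad D = 0.}
#' For positive parameters the system is stable; with R = 1 its DC gain is 1,
#' so the unit step response settles at 1.
#'
#' @param R Resistance.
#' @param L Inertance.
#' @param C Compliance.
#' @return An object of class `state_space_model` (usable with
#'   [simulate_response()], [to_transfer_function()], etc.) carrying
#'   `params = list(R, L, C)`.
#' @export
#' @examples
#' build_validation_system(1, 0.5, 0.25)$A  # [[-4, 4], [-2, 0]]
build_validation_system <- function(R, L, C) {
  check_positive_scalar(R, "R")
  check_positive_scalar(L, "L")
  check_positive_scalar(C, "C")
  A <- matrix(c(-1 / (R * C), 1 / C,
                -1 / L, 0),
              nrow = 2, byrow = TRUE)
  structure(
    list(A = A, B = c(0, 1 / L), Cout = c(1 / R, 0), D = 0,
         params = list(R = R, L = L, C = C), output = "resistor_current"),
    class = "state_space_model"
  )
}

#' Parameter-recovery experiment on the validation bench
#'
#' Generates the unit-step response of the known system `(R, L, C)`, then,
#' for each seed, runs the particle swarm over the 3-dimensional parameter
#' space to re-identify the system from that input/output pair. Reports the
#' estimates, per-parameter relative errors, and the maximum deviation of the
#' fitted system's step response from the true one as a fraction of the true
#' final value.
#'
#' @param truth Numeric length-3 vector or list `(R, L, C)`, all positive.
#' @param pso_config A [pso_config()] with `n_dims = 3`.
#' @param seeds Integer vector of RNG seeds (>= 1 seed).
#' @param horizon Record length in s; default 8 slowest time constants of the
#'   true system.
#' @param n_points Samples in the record; default 1001.
#' @return An object of class `recovery_report`: list with `true_params`,
#'   `estimates` (matrix, one row per seed), `relative_errors`,
#'   `step_deviation` (per seed), `objectives`, `seeds`.
#' @export
recovery_experiment <- function(truth, pso_config = capfit::pso_config(n_dims = 3L),
                                seeds = 1:5, horizon = NULL, n_points = 1001L) {
  truth <- as.numeric(unlist(truth))
  if (length(truth) != 3L || any(!is.finite(truth)) || any(truth <= 0)) {
    stop_invalid("'truth' must be three positive numbers (R, L, C)")
  }
  if (length(seeds) < 1L) stop_invalid("at least one seed is required")
  if (pso_config$n_dims != 3L) {
    stop_invalid("recovery runs over 3 dimensions (R, L, C)")
  }
  true_ss <- build_validation_system(truth[1], truth[2], truth[3])
  if (is.null(horizon)) horizon <- response_horizon(true_ss)
  times <- seq(0, horizon, length.out = n_points)
  input <- sampled_signal(times, rep(1, n_points))
  target <- simulate_response(true_ss, input, method = "discretize")
  final_value <- dc_gain(to_transfer_function(true_ss))
  obj <- function(x) {
    if (any(x <= 0)) return(DIVERGENCE_PENALTY)
    ss <- build_validation_system(x[1], x[2], x[3])
    if (!is_stable_matrix(ss$A)) return(DIVERGENCE_PENALTY)
    sim <- tryCatch(simulate_response(ss, input, method = "discretize"),
                    capfit_divergence_error = function(e) NULL)
    if (is.null(sim)) return(DIVERGENCE_PENALTY)
    error_integrals(target, sim)$total
  }
  est <- matrix(NA_real_, nrow = length(seeds), ncol = 3L,
                dimnames = list(NULL, c("R", "L", "C")))
  objectives <- numeric(length(seeds))
  step_dev <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- pso_config
    cfg$rng_seed <- seeds[i]
    res <- pso_optimize(obj, cfg)
    est[i, ] <- res$gbest_position
    objectives[i] <- res$gbest_value
    fit_ss <- build_validation_system(est[i, 1], est[i, 2], est[i, 3])
    fit_step <- simulate_response(fit_ss, input, method = "discretize")
    step_dev[i] <- max(abs(fit_step$values - target$values)) / abs(final_value)
  }
  rel_err <- abs(sweep(est, 2L, truth, "-")) / rep(truth, each = length(seeds))
  structure(
    list(true_params = stats::setNames(truth, c("R", "L", "C")),
         estimates = est, relative_errors = rel_err,
         step_deviation = step_dev, objectives = objectives,
         seeds = seeds),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery report (truth R =", x$true_params[1],
      ", L =", x$true_params[2], ", C =", x$true_params[3], ")\n")
  for (i in seq_along(x$seeds)) {
    cat(sprintf("  seed %d: R=%.5g L=%.5g C=%.5g | step dev %.3g%% | obj %.3g\n",
                x$seeds[i], x$estimates[i, 1], x$estimates[i, 2],
                x$estimates[i, 3], 100 * x$step_deviation[i],
                x$objectives[i]))
  }
  invisible(x)
}

#' Synthesize an input/target waveform pair from known circuit parameters
#'
#' Builds the systolic-pulse input from `spec`, simulates the circuit given
#' by `params`, and optionally adds white Gaussian noise to the output with
#' standard deviation `noise_sd` expressed as a fraction of the clean output
#' peak. Deterministic given `seed`. This stands in, for testing, for
#' clinically measured entry/exit capillary flow signals.
#'
#' @param params A [circuit_params()] object (the generating truth).
#' @param spec A [waveform_spec()].
#' @param noise_sd Noise standard deviation as a fraction of the clean target
#'   peak; `0` for a noiseless pair.
#' @param seed Integer RNG seed, or `NULL`.
#' @param output Output convention for [assemble_state_space()].
#' @return A list with `input` and `target` ([sampled_signal()] objects).
#' @export
synth_fit_pair <- function(params, spec = waveform_spec(), noise_sd = 0,
                           seed = NULL, output = "capacitor_effort") {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop_invalid("'noise_sd' must be a single nonnegative number")
  }
  input <- systolic_pulse(spec)
  ss <- assemble_state_space(params, output = output)
  target <- simulate_response(ss, input, method = "discretize")
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old_seed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
                add = TRUE)
      }
      set.seed(seed)
    }
    sd_abs <- noise_sd * max(abs(target$values))
    target <- sampled_signal(target$times,
                             target$values +
                               stats::rnorm(length(target$values), 0, sd_abs))
  }
  list(input = input, target = target)
}
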