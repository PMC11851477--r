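# Error-integral performance indices (ISE, ITSE), the composite fitting
# objective with its divergence guard, and helpers that connect a particle
# position to a simulated circuit response.

#' ISE and ITSE error integrals
#'
#' Integral performance indices of the error `e(t) = reference - simulated`
#' over the full record `[0, T]` by the trapezoidal rule:
#' ISE = integral of `e^2(t)`, ITSE = integral of `t e^2(t)`. ISE penalises
#' large early errors; ITSE weights errors near the end of the transient.
#'
#' @param reference,simulated [sampled_signal()] objects on identical grids.
#' @return An object of class `objective_breakdown`: list with `ise`, `itse`,
#'   `total = ise + itse`, `diverged = FALSE`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 0.001)
#' a <- sampled_signal(t, rep(1, length(t)))
#' b <- sampled_signal(t, rep(0, length(t)))
#' error_integrals(a, b)$ise  # 2
error_integrals <- function(reference, simulated) {
  if (!inherits(reference, "sampled_signal") ||
      !inherits(simulated, "sampled_signal")) {
    stop_invalid("both signals must be sampled_signal objects")
  }
  if (length(reference$times) != length(simulated$times) ||
      max(abs(reference$times - simulated$times)) >
        1e-9 * max(reference$times[2] - reference$times[1], 1e-300)) {
    stop_invalid("signals must share an identical time grid")
  }
  e <- reference$values - simulated$values
  t <- reference$times
  ise <- trapz_integral(t, e * e)
  itse <- trapz_integral(t, t * e * e)
  objective_breakdown(ise, itse, diverged = FALSE)
}

objective_breakdown <- function(ise, itse, diverged,
                                penalty = DIVERGENCE_PENALTY) {
  structure(
    list(ise = ise, itse = itse,
         total = if (diverged) penalty else ise + itse,
         diverged = diverged),
    class = "objective_breakdown"
  )
}

## Fixed penalty returned for parameter sets whose model is unstable or whose
## simulation blows up.
DIVERGENCE_PENALTY <- 1e12

#' Fitting objective for a candidate parameter position
#'
#' Maps a particle position (in the order R1, R2, L, C) to a circuit, guards
#' against divergence, simulates the response to `input`, and scores it
#' against `target` with ISE + ITSE. The guard declares divergence -- and
#' returns the fixed penalty `1e12` instead of simulating -- when any
#' parameter is non-positive or the state matrix has an eigenvalue with
#' nonnegative real part; a simulation that still produces non-finite values
#' is penalised the same way. All failures are encoded in the returned value,
#' never raised, so the optimizer can keep moving.
#'
#' @param position Numeric vector of length 4: R1, R2, L, C.
#' @param input Source waveform ([sampled_signal()]).
#' @param target Reference output waveform on the same grid.
#' @param output Output convention passed to [assemble_state_space()].
#' @return An `objective_breakdown` (see [error_integrals()]) with a
#'   `diverged` flag.
#' @export
objective_function <- function(position, input, target,
                               output = "capacitor_effort") {
  if (!is.numeric(position) || length(position) != 4L) {
    stop_invalid("'position' must be a numeric vector R1, R2, L, C")
  }
  if (any(!is.finite(position)) || any(position <= 0)) {
    return(objective_breakdown(NA_real_, NA_real_, diverged = TRUE))
  }
  params <- circuit_params(position[1], position[2], position[3], position[4])
  ss <- assemble_state_space(params, output = output)
  if (!is_stable_matrix(ss$A)) {
    return(objective_breakdown(NA_real_, NA_real_, diverged = TRUE))
  }
  sim <- tryCatch(
    simulate_response(ss, input, method = "discretize"),
    capfit_divergence_error = function(e) NULL
  )
  if (is.null(sim)) {
    return(objective_breakdown(NA_real_, NA_real_, diverged = TRUE))
  }
  error_integrals(target, sim)
}

## Eigenvalue stability test for a 2x2 (or general) state matrix.
is_stable_matrix <- function(A) {
  ev <- eigen(A, only.values = TRUE)$values
  all(Re(ev) < 0)
}
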