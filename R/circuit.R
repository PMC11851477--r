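# The two-state capillary circuit: parameter container, state-space
# realization, transfer function, and driving-point impedance.
#
# Circuit topology (electrical analogue): a series resistance R1 and
# inertance L feeding a parallel R2-C pair. States follow the energy-storage
# elements: x1 = inductor momentum (flux linkage) p, x2 = capacitor charge Q.
# The source is an effort (pressure/voltage) source; the reported output is
# the capacitor effort Q/C, i.e. the pressure across the compliant element.

#' Circuit parameters
#'
#' The four identifiable constants of the capillary equivalent circuit:
#' proximal resistance `R1`, distal (parallel) resistance `R2`, inertance `L`
#' and compliance `C`, in consistent abstract units. All must be strictly
#' positive and finite.
#'
#' @param R1,R2 Resistances.
#' @param L Inertance (inductance analogue).
#' @param C Compliance (capacitance analogue).
#' @return An object of class `circuit_params`.
#' @export
#' @examples
#' reference_circuit_params()
circuit_params <- function(R1, R2, L, C) {
  check_positive_scalar(R1, "R1")
  check_positive_scalar(R2, "R2")
  check_positive_scalar(L, "L")
  check_positive_scalar(C, "C")
  structure(list(R1 = R1, R2 = R2, L = L, C = C), class = "circuit_params")
}

#' Reference fitted circuit parameters
#'
#' The swarm-optimized capillary circuit constants reported for the study
#' cohort: R1 = 89.784, R2 = 426.55, L = 27.506, C = 0.00040675.
#'
#' @return A [circuit_params()] object.
#' @export
reference_circuit_params <- function() {
  circuit_params(R1 = 89.784, R2 = 426.55, L = 27.506, C = 0.00040675)
}

#' Assemble the two-state state-space model
#'
#' Realizes the capillary circuit as `xdot = A x + B u`, `y = Cout x + D u`
#' with states x1 = inductor momentum, x2 = capacitor charge, and the source
#' effort as input:
#' \deqn{A = \begin{pmatrix} -R_1/L & -1/C \\ 1/L & -1/(R_2 C) \end{pmatrix},
#'       \quad B = (1, 0)^T, \quad D = 0.}
#' With `output = "capacitor_effort"` (the default) the output is the effort
#' across the compliance, `y = x2/C`, giving `Cout = (0, 1/C)`; with
#' `output = "first_state"` the raw first state is returned
#' (`Cout = (1, 0)`), kept for comparison with the alternative output
#' convention.
#'
#' @param params A [circuit_params()] object.
#' @param output Output convention; see Details.
#' @return An object of class `state_space_model`: list with `A` (2x2), `B`
#'   (length-2), `Cout` (length-2), `D` (scalar 0), and `params`.
#' @export
#' @examples
#' ss <- assemble_state_space(reference_circuit_params())
#' ss$A
assemble_state_space <- function(params,
                                 output = c("capacitor_effort", "first_state")) {
  output <- match.arg(output)
  if (!inherits(params, "circuit_params")) {
    stop_invalid("'params' must be a circuit_params object")
  }
  R1 <- params$R1; R2 <- params$R2; L <- params$L; C <- params$C
  A <- matrix(c(-R1 / L, -1 / C,
                1 / L, -1 / (R2 * C)),
              nrow = 2, byrow = TRUE)
  B <- c(1, 0)
  Cout <- if (output == "capacitor_effort") c(0, 1 / C) else c(1, 0)
  structure(list(A = A, B = B, Cout = Cout, D = 0, params = params,
                 output = output),
            class = "state_space_model")
}

#' @export
print.state_space_model <- function(x, ...) {
  cat("2-state circuit model (output:", x$output, ")\nA:\n")
  print(x$A)
  cat("B:", x$B, "  Cout:", x$Cout, "  D:", x$D, "\n")
  invisible(x)
}

#' Transfer function of a state-space model
#'
#' Computes `G(s) = Cout (sI - A)^{-1} B + D` exactly for the 2-state model
#' via the adjugate of `sI - A`, returning the monic-denominator rational
#' form. For the default capacitor-effort output this equals
#' \deqn{G(s) = \frac{1/(LC)}{s^2 + (R_1/L + 1/(R_2 C)) s + (1 + R_1/R_2)/(LC)}.}
#'
#' @param ss A [state_space_model()] (or validation-bench model).
#' @return An object of class `transfer_function`: list with `num` and `den`
#'   coefficient vectors in descending powers of s, `den` monic of degree 2.
#' @export
#' @examples
#' to_transfer_function(assemble_state_space(reference_circuit_params()))
to_transfer_function <- function(ss) {
  if (!inherits(ss, "state_space_model")) {
    stop_invalid("'ss' must be a state_space_model")
  }
  A <- ss$A; B <- ss$B; Cv <- ss$Cout
  # den = det(sI - A) = s^2 - tr(A) s + det(A)
  den <- c(1, -(A[1, 1] + A[2, 2]), A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])
  # num(s) = Cv adj(sI - A) B: adj = [[s - a22, a12], [a21, s - a11]]
  num1 <- Cv[1] * B[1] + Cv[2] * B[2]
  num0 <- Cv[1] * (-A[2, 2] * B[1] + A[1, 2] * B[2]) +
          Cv[2] * (A[2, 1] * B[1] - A[1, 1] * B[2])
  num <- c(num1, num0)
  if (ss$D != 0) num <- num + ss$D * den[2:3]  # D folded in (D = 0 normally)
  if (abs(num[1]) <= 1e-14 * max(1, abs(num[2]))) num <- num[2]
  transfer_function(num, den)
}

#' Transfer function constructor
#'
#' @param num Numerator coefficients, descending powers; degree < 2.
#' @param den Denominator coefficients, descending powers; degree 2. Divided
#'   through so the stored denominator is monic.
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(num, den) {
  if (length(den) != 3L || den[1] == 0) {
    stop_invalid("'den' must be a degree-2 coefficient vector")
  }
  if (length(num) < 1L || length(num) > 2L) {
    stop_invalid("'num' must have degree < 2")
  }
  num <- num / den[1]
  den <- den / den[1]
  structure(list(num = as.numeric(num), den = as.numeric(den)),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, digits = 4, ...) {
  numtxt <- if (length(x$num) == 1L) format(signif(x$num, digits)) else
    sprintf("%s s + %s", format(signif(x$num[1], digits)),
            format(signif(x$num[2], digits)))
  cat(sprintf("G(s) = (%s) / (s^2 + %s s + %s)\n", numtxt,
              format(signif(x$den[2], digits)),
              format(signif(x$den[3], digits))))
  invisible(x)
}

#' Evaluate a transfer function at complex frequencies
#'
#' @param tf A [transfer_function()].
#' @param s Complex (or real) frequency values.
#' @return Complex values G(s).
#' @export
eval_tf <- function(tf, s) {
  num <- if (length(tf$num) == 1L) rep(tf$num, length(s)) else
    tf$num[1] * s + tf$num[2]
  num / (s^2 + tf$den[2] * s + tf$den[3])
}

#' DC gain of a transfer function
#'
#' @param tf A [transfer_function()].
#' @return `G(0)`, the ratio of the constant numerator and denominator terms.
#' @export
dc_gain <- function(tf) {
  tf$num[length(tf$num)] / tf$den[3]
}

#' Driving-point impedance of the capillary circuit
#'
#' Total impedance seen by the source at angular frequency `omega`:
#' `R1 + i*omega*L + R2 / (1 + i*R2*omega*C)` (series R1 and L feeding the
#' parallel R2-C pair). At omega = 0 the capacitor is open and the impedance
#' is the real sum `R1 + R2`; at high frequency the inertance dominates.
#'
#' @param params A [circuit_params()] object.
#' @param omega Angular frequency in rad/s (vectorised, must be >= 0).
#' @return Complex impedance values.
#' @export
input_impedance <- function(params, omega) {
  if (!inherits(params, "circuit_params")) {
    stop_invalid("'params' must be a circuit_params object")
  }
  if (!is.numeric(omega) || any(!is.finite(omega)) || any(omega < 0)) {
    stop_invalid("'omega' must be nonnegative and finite")
  }
  params$R1 + 1i * omega * params$L +
    params$R2 / (1 + 1i * params$R2 * omega * params$C)
}
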