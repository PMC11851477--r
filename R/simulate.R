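# Time-domain simulation of the 2-state models: an adaptive ODE path
# (default, via deSolve) and an exact per-step discretization path that is
# exact for piecewise-linear inputs and fast enough for use inside the
# optimizer's objective.

## Closed-form matrix exponential of a 2x2 matrix via its eigenvalues.
## For distinct eigenvalues l1 != l2:
##   expm(M) = (e^{l1} (M - l2 I) - e^{l2} (M - l1 I)) / (l1 - l2);
## for a repeated eigenvalue l: expm(M) = e^l (I + (M - l I)).
expm2 <- function(M) {
  tr <- M[1, 1] + M[2, 2]
  dt <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  disc <- sqrt(as.complex(tr * tr / 4 - dt))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  I2 <- diag(2)
  if (abs(l1 - l2) > 1e-9 * max(1, abs(l1), abs(l2))) {
    E <- (exp(l1) * (M + 0i - l2 * I2) - exp(l2) * (M + 0i - l1 * I2)) /
      (l1 - l2)
  } else {
    l <- tr / 2
    E <- exp(l) * (I2 + (M - l * I2)) + 0i
  }
  Re(E)
}

divergence_error <- function(time) {
  stop(errorCondition(
    sprintf("simulated trajectory became non-finite near t = %.6g", time),
    class = c("capfit_divergence_error", "capfit_error"),
    blow_up_time = time))
}

## Exact simulation on a uniform grid assuming the input is piecewise linear
## between samples (first-order hold). Returns the output sequence y.
## x_{k+1} = Ad x_k + B1 u_k + B2 (u_{k+1} - u_k), with
##   Ad = expm(A h), F = A^{-1}(Ad - I), G = A^{-1}(h Ad - F),
##   B1 = F B, B2 = (F - G/h) B.
## The output is advanced through the scalar difference equation implied by
## the Cayley-Hamilton relation Ad^2 = tr(Ad) Ad - det(Ad) I, evaluated with
## a single C-level recursive filter.
simulate_discretized <- function(ss, input, x0 = c(0, 0)) {
  A <- ss$A; B <- ss$B; Cv <- ss$Cout
  h <- input$times[2] - input$times[1]
  u <- input$values
  n <- length(u)
  Ad <- expm2(A * h)
  detA <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (!is.finite(detA) || detA == 0) {
    stop_invalid("state matrix is singular; cannot discretize")
  }
  # analytic 2x2 inverse: robust for the badly scaled matrices that arise
  # from extreme particle positions during optimization
  Ainv <- matrix(c(A[2, 2], -A[1, 2], -A[2, 1], A[1, 1]), 2, 2,
                 byrow = TRUE) / detA
  F <- Ainv %*% (Ad - diag(2))
  G <- Ainv %*% (h * Ad - F)
  B1 <- as.numeric(F %*% B)
  B2 <- as.numeric((F - G / h) %*% B)
  du <- c(diff(u), 0)
  # forcing applied between sample k and k+1
  w1 <- B1[1] * u + B2[1] * du
  w2 <- B1[2] * u + B2[2] * du
  a1 <- Ad[1, 1] + Ad[2, 2]
  a2 <- Ad[1, 1] * Ad[2, 2] - Ad[1, 2] * Ad[2, 1]
  # y_{k+2} = a1 y_{k+1} - a2 y_k + Cv (Ad - a1 I) w_k + Cv w_{k+1}
  M <- Ad - a1 * diag(2)
  p <- (Cv[1] * M[1, 1] + Cv[2] * M[2, 1]) * w1 +
       (Cv[1] * M[1, 2] + Cv[2] * M[2, 2]) * w2
  q <- Cv[1] * w1 + Cv[2] * w2
  y <- numeric(n)
  y[1] <- sum(Cv * x0)
  if (n >= 2L) {
    x1 <- as.numeric(Ad %*% x0) + c(w1[1], w2[1])
    y[2] <- sum(Cv * x1)
  }
  if (n >= 3L) {
    forcing <- p[1:(n - 2L)] + q[2:(n - 1L)]
    # recursive filter with explicit initial conditions y[1], y[2]
    z <- stats::filter(forcing, c(a1, -a2), method = "recursive",
                       init = c(y[2], y[1]))
    y[3:n] <- as.numeric(z)
  }
  if (ss$D != 0) y <- y + ss$D * u
  y
}

#' Simulate the response of a state-space model to a sampled input
#'
#' Integrates `xdot = A x + B u(t)`, `y = Cout x + D u` over the input's time
#' grid. Two integration paths are available:
#' \describe{
#'   \item{`"adaptive"`}{(default) adaptive multistep integration via
#'     \pkg{deSolve} (`lsoda`) with `rtol = 1e-8`, `atol = 1e-12`, the input
#'     interpolated linearly between samples.}
#'   \item{`"discretize"`}{exact per-step discretization (matrix exponential,
#'     first-order hold), exact for piecewise-linear inputs and much faster;
#'     used internally by the fitting objective.}
#' }
#'
#' @param ss A [state_space_model()].
#' @param input A [sampled_signal()] on a uniform grid.
#' @param x0 Initial state (length 2); default zero.
#' @param method `"adaptive"` or `"discretize"`.
#' @param rtol,atol Tolerances for the adaptive path.
#' @return A [sampled_signal()] with the output `y` on the input grid.
#' @export
#' @examples
#' ss <- assemble_state_space(reference_circuit_params())
#' u <- systolic_pulse(waveform_spec(peak_flow = 1, n_cycles = 2L))
#' y <- simulate_response(ss, u)
simulate_response <- function(ss, input, x0 = c(0, 0),
                              method = c("adaptive", "discretize"),
                              rtol = 1e-8, atol = 1e-12) {
  method <- match.arg(method)
  if (!inherits(ss, "state_space_model")) {
    stop_invalid("'ss' must be a state_space_model")
  }
  if (!inherits(input, "sampled_signal")) {
    stop_invalid("'input' must be a sampled_signal")
  }
  if (length(x0) != 2L || !all(is.finite(x0))) {
    stop_invalid("'x0' must be a finite length-2 vector")
  }
  if (method == "discretize") {
    y <- simulate_discretized(ss, input, x0)
    if (!all(is.finite(y))) {
      divergence_error(input$times[which(!is.finite(y))[1]])
    }
    return(sampled_signal(input$times, y))
  }
  ufun <- stats::approxfun(input$times, input$values, rule = 2)
  A <- ss$A; B <- ss$B
  deriv <- function(t, x, parms) list(A %*% x + B * ufun(t))
  sol <- tryCatch(
    deSolve::ode(y = x0, times = input$times, func = deriv, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(sol) || nrow(sol) < length(input$times) ||
      !all(is.finite(sol[, 2:3]))) {
    bad_t <- if (is.null(sol)) input$times[1] else {
      idx <- which(!is.finite(sol[, 2]) | !is.finite(sol[, 3]))
      if (length(idx)) sol[idx[1], 1] else sol[nrow(sol), 1]
    }
    divergence_error(bad_t)
  }
  y <- sol[, 2] * ss$Cout[1] + sol[, 3] * ss$Cout[2] + ss$D * input$values
  sampled_signal(input$times, y)
}

## Default horizon: 8 slowest time constants, i.e. 8 / min |Re(pole)|.
response_horizon <- function(ss, n_time_constants = 8) {
  ev <- eigen(ss$A, only.values = TRUE)$values
  rates <- -Re(ev)
  if (any(rates <= 0)) {
    stop_invalid("response horizon is only defined for stable models")
  }
  n_time_constants / min(rates)
}

#' Unit step response
#'
#' Response of the model to a unit step input from rest, over a horizon of
#' `n_time_constants` slowest time constants (default 8), so that the output
#' has settled to its DC gain by the end of the record.
#'
#' @param ss A [state_space_model()].
#' @param n_points Number of samples; default 2000.
#' @param n_time_constants Horizon in units of the slowest time constant.
#' @param horizon Explicit horizon in s (overrides `n_time_constants`).
#' @return A [sampled_signal()].
#' @export
step_response <- function(ss, n_points = 2000L, n_time_constants = 8,
                          horizon = NULL) {
  if (is.null(horizon)) horizon <- response_horizon(ss, n_time_constants)
  times <- seq(0, horizon, length.out = n_points)
  u <- sampled_signal(times, rep(1, n_points))
  simulate_response(ss, u, method = "discretize")
}

#' Unit impulse response
#'
#' Closed-form impulse response `h(t) = Cout expm(A t) B`, evaluated through
#' the partial-fraction expansion of the transfer function over the
#' denominator roots (exact, no numerical integration).
#'
#' @inheritParams step_response
#' @return A [sampled_signal()].
#' @export
impulse_response <- function(ss, n_points = 2000L, n_time_constants = 8,
                             horizon = NULL) {
  if (is.null(horizon)) horizon <- response_horizon(ss, n_time_constants)
  times <- seq(0, horizon, length.out = n_points)
  tf <- to_transfer_function(ss)
  roots <- polyroot(rev(tf$den))
  l1 <- roots[1]; l2 <- roots[2]
  numf <- function(s) if (length(tf$num) == 1L) tf$num + 0 * s else
    tf$num[1] * s + tf$num[2]
  if (abs(l1 - l2) > 1e-9 * max(1, Mod(l1))) {
    r1 <- numf(l1) / (l1 - l2)
    r2 <- numf(l2) / (l2 - l1)
    h <- Re(r1 * exp(l1 * times) + r2 * exp(l2 * times))
  } else {
    # repeated root: h(t) = (n1 + (n0 + n1 l) t) e^{l t}
    n1 <- if (length(tf$num) == 2L) tf$num[1] else 0
    n0 <- tf$num[length(tf$num)]
    h <- Re((n1 + (n0 + n1 * l1) * times) * exp(l1 * times))
  }
  sampled_signal(times, h)
}
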