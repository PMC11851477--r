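# Shared generators and independent oracles for the test suite.

# random strictly positive circuit parameters spanning several decades;
# any positive parameter set yields a stable state matrix
rand_circuit_params <- function() {
  circuit_params(R1 = 10^runif(1, -2, 2), R2 = 10^runif(1, -2, 2),
                 L = 10^runif(1, -2, 2), C = 10^runif(1, -3, 1))
}

# moderately scaled draws for time-domain comparisons: keeps the two state
# rates within a few decades so a single uniform grid resolves both modes
rand_moderate_params <- function() {
  circuit_params(R1 = 10^runif(1, -0.5, 1), R2 = 10^runif(1, -0.5, 1),
                 L = 10^runif(1, -0.5, 0.5), C = 10^runif(1, -1.5, 0))
}

# exact zero-order-hold stepping oracle built on Matrix::expm, independent
# of the package's own closed-form 2x2 exponential
zoh_oracle <- function(ss, input, x0 = c(0, 0)) {
  h <- input$times[2] - input$times[1]
  Ad <- as.matrix(Matrix::expm(Matrix::Matrix(ss$A * h)))
  FB <- solve(ss$A, (Ad - diag(2)) %*% ss$B)
  n <- length(input$values)
  x <- x0
  y <- numeric(n)
  y[1] <- sum(ss$Cout * x0)
  for (k in 2:n) {
    x <- Ad %*% x + FB * input$values[k - 1L]
    y[k] <- sum(ss$Cout * x)
  }
  y
}

# evaluate a transfer function's rational form at one complex point from raw
# state-space matrices, fully independently of to_transfer_function()
tf_point_oracle <- function(ss, s) {
  M <- s * diag(2) - ss$A
  drop((ss$Cout %*% solve(M, ss$B)) + ss$D)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected), rel_tol * max(abs(expected), 1e-300))
}
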