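test_that("state-space assembly realizes the derivation closed forms", {
  ss <- assemble_state_space(reference_circuit_params())
  expect_equal(signif(ss$A[1, 1], 5), -3.2642)
  expect_equal(signif(ss$A[2, 2], 5), -5.7637)
  expect_equal(ss$B, c(1, 0))
  expect_equal(ss$D, 0)

  unit <- assemble_state_space(circuit_params(1, 1, 1, 1))
  expect_equal(unit$A, matrix(c(-1, -1, 1, -1), 2, byrow = TRUE))
  expect_equal(unit$Cout, c(0, 1))

  # literal first-state output convention available behind the flag
  alt <- assemble_state_space(circuit_params(1, 1, 1, 1), output = "first_state")
  expect_equal(alt$Cout, c(1, 0))

  expect_error(circuit_params(-1, 1, 1, 1), class = "capfit_invalid_input")
})

test_that("transfer function matches the symbolic closed form and point oracle", {
  unit <- to_transfer_function(assemble_state_space(circuit_params(1, 1, 1, 1)))
  expect_equal(unit$num, 1)
  expect_equal(unit$den, c(1, 2, 2))

  set.seed(21)
  for (i in 1:50) {
    p <- rand_circuit_params()
    ss <- assemble_state_space(p)
    tf <- to_transfer_function(ss)
    # closed form of the capacitor-effort output
    expect_rel_equal(tf$num[length(tf$num)], 1 / (p$L * p$C), 1e-12)
    expect_rel_equal(tf$den[2], p$R1 / p$L + 1 / (p$R2 * p$C), 1e-12)
    expect_rel_equal(tf$den[3], (1 + p$R1 / p$R2) / (p$L * p$C), 1e-12)
    # independent numeric evaluation of Cout (sI - A)^-1 B at a test point
    s0 <- complex(real = 0.3, imaginary = 1.7)
    expect_lt(Mod(eval_tf(tf, s0) - tf_point_oracle(ss, s0)),
              1e-9 * Mod(tf_point_oracle(ss, s0)))
  }
})

test_that("DC gain equals the ratio of constant coefficients", {
  set.seed(22)
  for (i in 1:10) {
    p <- rand_circuit_params()
    tf <- to_transfer_function(assemble_state_space(p))
    expect_rel_equal(dc_gain(tf), 1 / (1 + p$R1 / p$R2), 1e-12)
  }
})

test_that("driving-point impedance follows the series-parallel formula", {
  p <- reference_circuit_params()
  z0 <- input_impedance(p, 0)
  expect_equal(Re(z0), 516.334)
  expect_equal(Im(z0), 0)
  # inductive asymptote: |Z| grows linearly in omega
  ratio <- Mod(input_impedance(p, 1e7)) / Mod(input_impedance(p, 1e6))
  expect_equal(ratio, 10, tolerance = 1e-3)
  expect_error(input_impedance(p, -1), class = "capfit_invalid_input")
})

test_that("simulation reproduces rest, steady state and frequency response", {
  ss <- assemble_state_space(reference_circuit_params())
  t <- seq(0, 2, by = 0.002)

  # zero input from rest stays at rest
  zero <- simulate_response(ss, sampled_signal(t, numeric(length(t))))
  expect_true(all(zero$values == 0))

  # unit step settles at the DC gain 89.38/108.2
  stp <- simulate_response(ss, sampled_signal(t, rep(1, length(t))))
  expect_equal(signif(stp$values[length(t)], 3), 0.826)

  # long-run sinusoidal amplitude matches |G(i omega)|
  tf <- to_transfer_function(ss)
  omega <- 8
  tl <- seq(0, 30, by = 0.005)
  sine <- simulate_response(ss, sampled_signal(tl, sin(omega * tl)))
  tail_amp <- max(abs(sine$values[tl > 25]))
  expect_equal(tail_amp, Mod(eval_tf(tf, 1i * omega)), tolerance = 0.01)
})

test_that("adaptive and exact-discretization paths agree with the expm oracle", {
  skip_if_not_installed("Matrix")
  set.seed(23)
  for (i in 1:5) {
    ss <- assemble_state_space(rand_moderate_params())
    rates <- -Re(eigen(ss$A, only.values = TRUE)$values)
    horizon <- 8 / min(rates)
    n <- min(4000L, max(400L, ceiling(4 * horizon * max(rates))))
    t <- seq(0, horizon, length.out = n)
    # constant input: zero-order-hold oracle is exact
    u_const <- sampled_signal(t, rep(1, n))
    y_ad <- simulate_response(ss, u_const, method = "adaptive",
                              rtol = 1e-10, atol = 1e-14)$values
    y_or <- zoh_oracle(ss, u_const)
    expect_lt(max(abs(y_ad - y_or)), 1e-6 * max(abs(y_or)))
    # smooth input: both package paths integrate the same interpolated input
    u_sin <- sampled_signal(t, sin(2 * pi * t / horizon))
    y1 <- simulate_response(ss, u_sin, method = "adaptive",
                            rtol = 1e-10, atol = 1e-14)$values
    y2 <- simulate_response(ss, u_sin, method = "discretize")$values
    expect_lt(max(abs(y1 - y2)), 1e-6 * max(abs(y2), 1e-12))
  }
})

test_that("divergent trajectories raise a divergence error with a blow-up time", {
  unstable <- structure(
    list(A = matrix(c(60, 0, 0, 60), 2), B = c(1, 0), Cout = c(1, 0), D = 0,
         params = NULL, output = "first_state"),
    class = "state_space_model")
  t <- seq(0, 20, by = 0.01)
  err <- tryCatch(
    simulate_response(unstable, sampled_signal(t, rep(1, length(t))),
                      method = "discretize"),
    capfit_divergence_error = function(e) e)
  expect_s3_class(err, "capfit_divergence_error")
  expect_true(is.finite(err$blow_up_time))
})

test_that("step response shows damping-consistent transients", {
  # reference circuit is underdamped: the step overshoots its final value
  ss <- assemble_state_space(reference_circuit_params())
  stp <- step_response(ss)
  final <- dc_gain(to_transfer_function(ss))
  expect_gt(max(stp$values), 1.02 * final)
  expect_equal(stp$values[length(stp$values)], final, tolerance = 1e-3)

  # critically damped G = 1/(s^2 + 2s + 1): no overshoot
  crit <- build_validation_system(R = 1, L = 2, C = 0.5)
  expect_equal(to_transfer_function(crit)$den, c(1, 2, 1))
  stc <- step_response(crit)
  expect_lte(max(stc$values), 1 + 1e-9)
})

test_that("impulse response integrates to the DC gain", {
  for (p in list(reference_circuit_params(), circuit_params(2, 5, 0.3, 0.1))) {
    ss <- assemble_state_space(p)
    h <- impulse_response(ss, n_points = 4000L, n_time_constants = 14)
    area <- sum(diff(h$times) * (h$values[-1] + h$values[-length(h$values)]) / 2)
    expect_equal(area, dc_gain(to_transfer_function(ss)), tolerance = 0.005)
  }
})
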