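test_that("error integrals match closed-form values", {
  t2 <- seq(0, 2, by = 0.001)
  ones <- sampled_signal(t2, rep(1, length(t2)))
  zeros <- sampled_signal(t2, numeric(length(t2)))
  br <- error_integrals(ones, zeros)
  expect_equal(br$ise, 2)           # integral of 1 over [0, 2]
  expect_equal(br$itse, 2)          # integral of t over [0, 2]
  expect_equal(br$total, br$ise + br$itse)
  expect_false(br$diverged)

  same <- error_integrals(ones, ones)
  expect_equal(same$ise, 0)
  expect_equal(same$itse, 0)

  tp <- seq(0, pi, length.out = 20001)
  sine <- sampled_signal(tp, sin(tp))
  zp <- sampled_signal(tp, numeric(length(tp)))
  br2 <- error_integrals(sine, zp)
  expect_equal(br2$ise, pi / 2, tolerance = 1e-4)       # int sin^2 over [0, pi]
  expect_equal(br2$itse, pi^2 / 4, tolerance = 1e-4)    # int t sin^2 over [0, pi]

  t3 <- seq(0, 2, by = 0.002)
  expect_error(error_integrals(ones, sampled_signal(t3, rep(1, length(t3)))),
               class = "capfit_invalid_input")
})

test_that("objective is near zero at the generating parameters and penalises failures", {
  truth <- reference_circuit_params()
  pair <- synth_fit_pair(truth, waveform_spec(peak_flow = 1), noise_sd = 0)
  energy <- error_integrals(pair$target,
                            sampled_signal(pair$target$times,
                                           numeric(length(pair$target$times))))$total
  at_truth <- objective_function(c(truth$R1, truth$R2, truth$L, truth$C),
                                 pair$input, pair$target)
  expect_lt(at_truth$total, 1e-20 * energy)
  expect_false(at_truth$diverged)

  # non-positive entries are encoded as the fixed penalty, never raised
  bad <- objective_function(c(-1, 1, 1, 1), pair$input, pair$target)
  expect_true(bad$diverged)
  expect_equal(bad$total, 1e12)

  # a position clamped at the lower search bound still evaluates finitely
  lo <- objective_function(rep(1e-6, 4), pair$input, pair$target)
  expect_true(is.finite(lo$total))
})

test_that("instability is detected by the eigenvalue guard", {
  expect_false(capfit:::is_stable_matrix(matrix(c(1, 0, 0, -1), 2)))
  expect_true(capfit:::is_stable_matrix(matrix(c(-1, -1, 1, -1), 2, byrow = TRUE)))
  # every strictly positive parameter set yields a stable circuit matrix
  set.seed(31)
  for (i in 1:50) {
    expect_true(capfit:::is_stable_matrix(assemble_state_space(rand_circuit_params())$A))
  }
})

test_that("inertia decays linearly from omega0 to omegaf", {
  cfg <- pso_config(max_iter = 500L)
  expect_equal(inertia_update(0.9, cfg), 0.8984)
  w <- cfg$omega0
  for (k in 1:500) w <- inertia_update(w, cfg)
  expect_equal(w, 0.1, tolerance = 1e-12)

  const <- pso_config(omega0 = 0.5, omegaf = 0.5)
  expect_equal(inertia_update(0.5, const), 0.5)
})

test_that("swarm step follows the velocity/position update equations", {
  cfg <- pso_config(n_particles = 3L, n_dims = 2L, x_min = -10, x_max = 10,
                    cg = 2, cs = 2, v_max = 100)
  x <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  v <- matrix(0.1, 3, 2)
  pb <- x + 0.5
  gb <- c(0, 0)

  # oracle replays the same RNG stream used inside pso_step
  set.seed(77)
  r1 <- matrix(runif(6), 3, 2); r2 <- matrix(runif(6), 3, 2)
  v_exp <- 0.7 * v + 2 * r1 * (pb - x) + 2 * r2 * (matrix(gb, 3, 2, byrow = TRUE) - x)
  v_exp <- pmin(pmax(v_exp, -100), 100)
  x_exp <- pmin(pmax(x + v_exp, -10), 10)
  set.seed(77)
  st <- pso_step(x, v, pb, gb, omega = 0.7, config = cfg)
  expect_equal(st$velocities, v_exp)
  expect_equal(st$positions, x_exp)

  # with zero acceleration and unit inertia, positions advance by velocity
  cfg0 <- pso_config(n_particles = 2L, n_dims = 2L, x_min = -10, x_max = 10,
                     cg = 0, cs = 0, v_max = 100)
  x0 <- matrix(0, 2, 2); v0 <- matrix(1, 2, 2)
  st0 <- pso_step(x0, v0, x0, c(0, 0), omega = 1, config = cfg0)
  expect_equal(st0$velocities, v0)
  expect_equal(st0$positions, x0 + v0)

  # a particle sitting at its own pbest = gbest with zero velocity stays put
  xf <- matrix(c(1, 1), 1, 2)
  stf <- pso_step(xf, matrix(0, 1, 2), xf, c(1, 1), omega = 0.9, config = cfg0)
  expect_equal(stf$positions, xf)
})

test_that("optimizer is deterministic, monotone and respects bounds", {
  sphere <- function(x) sum(x^2)
  cfg <- pso_config(n_dims = 2L, x_min = -5, x_max = 5, max_iter = 120L,
                    rng_seed = 7L)
  r1 <- pso_optimize(sphere, cfg)
  r2 <- pso_optimize(sphere, cfg)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$convergence_trace) <= 0))
  expect_equal(r1$gbest_value, r1$convergence_trace[length(r1$convergence_trace)])
  expect_true(all(r1$pbest_positions >= -5 & r1$pbest_positions <= 5))
  expect_lt(r1$gbest_value, 1e-4)
  expect_equal(r1$evaluations, 20 * 121)
})
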