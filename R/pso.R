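# Particle swarm optimization with linearly decaying inertia, velocity
# clamping and boundary repositioning, as used for circuit identification.

#' PSO configuration
#'
#' Hyperparameters of the swarm. Defaults follow the identification setup:
#' 20 particles, 500 iterations, 4 dimensions, position bounds
#' `[1e-6, 450]`, inertia decayed linearly from 0.9 to 0.1, and initial
#' velocities drawn uniformly in `±2 * (x_max - x_min)`. The cognitive and
#' social coefficients default to the canonical `cg = cs = 2`; the velocity
#' clamp defaults to half the search range per dimension.
#'
#' @param n_particles Swarm size S (>= 2).
#' @param max_iter Number of iterations.
#' @param n_dims Number of dimensions N.
#' @param x_min,x_max Position bounds, scalars or length-N vectors.
#' @param omega0,omegaf Initial and final inertia weights (0 < omegaf <=
#'   omega0 < 2).
#' @param cg,cs Cognitive (personal-best) and social (global-best)
#'   acceleration coefficients.
#' @param v_init_scale Initial velocities are uniform in
#'   `±v_init_scale * (x_max - x_min)`.
#' @param v_max Velocity clamp per dimension; default
#'   `0.5 * (x_max - x_min)`.
#' @param rng_seed Integer seed making the run reproducible, or `NULL`.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(n_particles = 20L, max_iter = 500L, n_dims = 4L,
                       x_min = 1e-6, x_max = 450,
                       omega0 = 0.9, omegaf = 0.1,
                       cg = 2.0, cs = 2.0,
                       v_init_scale = 2,
                       v_max = NULL,
                       rng_seed = NULL) {
  if (n_particles < 2L) stop_invalid("'n_particles' must be >= 2")
  if (max_iter < 1L) stop_invalid("'max_iter' must be >= 1")
  if (n_dims < 1L) stop_invalid("'n_dims' must be >= 1")
  x_min <- rep_len(as.numeric(x_min), n_dims)
  x_max <- rep_len(as.numeric(x_max), n_dims)
  if (any(x_min >= x_max)) stop_invalid("'x_min' must be < 'x_max' elementwise")
  if (!(omegaf > 0 && omegaf <= omega0 && omega0 < 2)) {
    stop_invalid("inertia weights must satisfy 0 < omegaf <= omega0 < 2")
  }
  if (is.null(v_max)) v_max <- 0.5 * (x_max - x_min)
  v_max <- rep_len(as.numeric(v_max), n_dims)
  structure(
    list(n_particles = as.integer(n_particles), max_iter = as.integer(max_iter),
         n_dims = as.integer(n_dims), x_min = x_min, x_max = x_max,
         omega0 = omega0, omegaf = omegaf, cg = cg, cs = cs,
         v_init_scale = v_init_scale, v_max = v_max, rng_seed = rng_seed),
    class = "pso_config"
  )
}

#' Linear inertia-weight update
#'
#' One step of the linear decay `omega_{k+1} = omega_k +
#' (omegaf - omega0) / max_iter`, which carries the inertia from `omega0` to
#' `omegaf` across exactly `max_iter` updates.
#'
#' @param omega_k Current inertia weight.
#' @param config A [pso_config()].
#' @return The updated inertia weight.
#' @export
inertia_update <- function(omega_k, config) {
  omega_k + (config$omegaf - config$omega0) / config$max_iter
}

#' One swarm update step
#'
#' Velocity update `v' = omega*v + cg*r1*(pbest - x) + cs*r2*(gbest - x)`
#' with fresh `r1, r2 ~ U(0,1)` drawn per particle and per dimension,
#' followed by velocity clamping to `±v_max`, the position update
#' `x' = x + v'`, and repositioning of out-of-bounds particles onto the
#' violated bound. The velocity component of a repositioned dimension is
#' negated (reflected), so a particle that hits a wall re-enters the
#' interior on the next step; zeroing it instead lets a dimension collapse
#' permanently once a swarm's best positions touch a bound, because the
#' velocity update is then identically zero there.
#'
#' @param positions,velocities S x N matrices.
#' @param pbest S x N matrix of personal best positions.
#' @param gbest Length-N global best position.
#' @param omega Current inertia weight.
#' @param config A [pso_config()].
#' @return A list with updated `positions` and `velocities`.
#' @export
pso_step <- function(positions, velocities, pbest, gbest, omega, config) {
  S <- nrow(positions); N <- ncol(positions)
  r1 <- matrix(stats::runif(S * N), S, N)
  r2 <- matrix(stats::runif(S * N), S, N)
  gb <- matrix(gbest, S, N, byrow = TRUE)
  v <- omega * velocities +
    config$cg * r1 * (pbest - positions) +
    config$cs * r2 * (gb - positions)
  vmax <- matrix(config$v_max, S, N, byrow = TRUE)
  v <- pmin(pmax(v, -vmax), vmax)
  x <- positions + v
  lo <- matrix(config$x_min, S, N, byrow = TRUE)
  hi <- matrix(config$x_max, S, N, byrow = TRUE)
  clamped <- x < lo | x > hi
  x <- pmin(pmax(x, lo), hi)
  v[clamped] <- -v[clamped]
  list(positions = x, velocities = v)
}

#' Run the particle swarm optimizer
#'
#' Minimises `objective` over the box `[x_min, x_max]^N`. Positions are
#' initialised uniformly in the bounds and velocities uniformly in
#' `±v_init_scale * (x_max - x_min)`; each iteration evaluates all
#' particles, updates the personal and global bests, advances the swarm with
#' [pso_step()] and decays the inertia with [inertia_update()]. The run is
#' fully deterministic given `config$rng_seed`.
#'
#' @param objective Function taking a length-N numeric position and returning
#'   either a single number or a list with a `total` element (e.g.
#'   [objective_function()]'s breakdown).
#' @param config A [pso_config()].
#' @return An object of class `pso_result`: list with `gbest_position`,
#'   `gbest_value`, `pbest_positions`, `pbest_values`, `convergence_trace`
#'   (best objective after each iteration, non-increasing), and
#'   `evaluations`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- pso_optimize(sphere, pso_config(n_dims = 2L, x_min = -5, x_max = 5,
#'                                        max_iter = 50L, rng_seed = 1L))
#' res$gbest_value
pso_optimize <- function(objective, config) {
  if (!inherits(config, "pso_config")) {
    stop_invalid("'config' must be a pso_config")
  }
  if (!is.null(config$rng_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(config$rng_seed)
  }
  S <- config$n_particles; N <- config$n_dims
  lo <- matrix(config$x_min, S, N, byrow = TRUE)
  hi <- matrix(config$x_max, S, N, byrow = TRUE)
  positions <- lo + matrix(stats::runif(S * N), S, N) * (hi - lo)
  vspan <- config$v_init_scale * (hi - lo)
  velocities <- matrix(stats::runif(S * N, -1, 1), S, N) * vspan
  eval_one <- function(x) {
    val <- objective(x)
    if (is.list(val)) val <- val$total
    if (!is.numeric(val) || length(val) != 1L || is.na(val)) {
      stop_invalid("objective must return a finite number or a list with $total")
    }
    val
  }
  pbest <- positions
  pbest_val <- apply(positions, 1L, eval_one)
  evals <- S
  gi <- which.min(pbest_val)
  gbest <- pbest[gi, ]
  gbest_val <- pbest_val[gi]
  omega <- config$omega0
  trace <- numeric(config$max_iter)
  for (k in seq_len(config$max_iter)) {
    stepped <- pso_step(positions, velocities, pbest, gbest, omega, config)
    positions <- stepped$positions
    velocities <- stepped$velocities
    vals <- apply(positions, 1L, eval_one)
    evals <- evals + S
    improved <- vals < pbest_val
    pbest[improved, ] <- positions[improved, ]
    pbest_val[improved] <- vals[improved]
    gi <- which.min(pbest_val)
    if (pbest_val[gi] < gbest_val) {
      gbest_val <- pbest_val[gi]
      gbest <- pbest[gi, ]
    }
    trace[k] <- gbest_val
    omega <- inertia_update(omega, config)
  }
  structure(
    list(gbest_position = gbest, gbest_value = gbest_val,
         pbest_positions = pbest, pbest_values = pbest_val,
         convergence_trace = trace, evaluations = evals),
    class = "pso_result"
  )
}

#' @export
print.pso_result <- function(x, ...) {
  cat("PSO result:\n")
  cat("  gbest value:", format(x$gbest_value, digits = 6), "\n")
  cat("  gbest position:", paste(format(x$gbest_position, digits = 6),
                                 collapse = ", "), "\n")
  cat("  evaluations:", x$evaluations, "\n")
  invisible(x)
}

#' Fit the capillary circuit to an input/target waveform pair
#'
#' Convenience wrapper: runs [pso_optimize()] on [objective_function()] for
#' the given signals and returns the fitted [circuit_params()] together with
#' the optimizer result and the objective breakdown at the optimum.
#'
#' @param input,target [sampled_signal()] objects on the same grid.
#' @param config A [pso_config()] with `n_dims = 4`.
#' @param output Output convention for [assemble_state_space()].
#' @return A list with `params`, `result` (the `pso_result`), `breakdown`,
#'   `tf` (fitted transfer function).
#' @export
fit_circuit <- function(input, target, config = pso_config(),
                        output = "capacitor_effort") {
  if (config$n_dims != 4L) {
    stop_invalid("circuit fitting requires a 4-dimensional pso_config")
  }
  obj <- function(x) objective_function(x, input, target, output = output)
  res <- pso_optimize(obj, config)
  params <- circuit_params(res$gbest_position[1], res$gbest_position[2],
                           res$gbest_position[3], res$gbest_position[4])
  list(params = params,
       result = res,
       breakdown = obj(res$gbest_position),
       tf = to_transfer_function(assemble_state_space(params, output = output)))
}
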