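# Particle swarm optimization (global-best topology, box constraints).

#' Particle swarm configuration
#'
#' @param n_particles swarm size, >= 2.
#' @param dims number of search dimensions.
#' @param lower,upper numeric vectors (length `dims` or 1, recycled) giving
#'   the per-dimension search box; `lower < upper`.
#' @param c1,c2 cognitive and social acceleration factors, >= 0.
#' @param inertia inertia weight on the previous velocity. The default 1
#'   reproduces the bare velocity update `V + c1 r1 (pbest - H) + c2 r2
#'   (gbest - H)`; values below 1 damp the swarm.
#' @param inertia_end if non-`NULL`, the inertia decays linearly from
#'   `inertia` to `inertia_end` over the run (a common convergence aid).
#' @param max_iters iteration budget, >= 1.
#' @param init_vel_frac initial velocities are uniform on
#'   `+/- init_vel_frac * (upper - lower)` per dimension.
#' @param seed integer RNG seed; runs are deterministic given the config.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(n_particles = 30, dims, lower, upper,
                         c1 = 1.5, c2 = 1.5, inertia = 1,
                         inertia_end = NULL, max_iters = 100,
                         init_vel_frac = 0.5, seed = 1L) {
  lower <- rep_len(as.numeric(lower), dims)
  upper <- rep_len(as.numeric(upper), dims)
  if (n_particles < 2) abort("`n_particles` must be >= 2.")
  if (any(lower >= upper)) abort("Each `lower` must be < `upper`.")
  if (c1 < 0 || c2 < 0) abort("`c1` and `c2` must be >= 0.")
  if (max_iters < 1) abort("`max_iters` must be >= 1.")
  structure(list(n_particles = as.integer(n_particles), dims = as.integer(dims),
                 lower = lower, upper = upper, c1 = c1, c2 = c2,
                 inertia = inertia, inertia_end = inertia_end,
                 max_iters = as.integer(max_iters),
                 init_vel_frac = init_vel_frac, seed = as.integer(seed)),
            class = "swarm_config")
}

#' Initialize a swarm
#'
#' Positions uniform in the box; velocities uniform on
#' `+/- init_vel_frac * (upper - lower)`; personal bests start at the initial
#' positions. Fitnesses are `NA` until the first evaluation.
#'
#' @param config a [swarm_config()].
#' @return A `swarm_state` list with `positions` and `velocities`
#'   (`n_particles x dims` matrices), `pbest_pos`, `pbest_fit`, `gbest_pos`,
#'   `gbest_fit`, `iter`.
#' @export
init_swarm <- function(config) {
  if (!inherits(config, "swarm_config")) abort("`config` must be a swarm_config.")
  z <- config$n_particles; n <- config$dims
  withr::with_seed(derive_seed(config$seed, "init"), {
    pos <- sapply(seq_len(n), function(d) runif(z, config$lower[d], config$upper[d]))
    span <- config$init_vel_frac * (config$upper - config$lower)
    vel <- sapply(seq_len(n), function(d) runif(z, -span[d], span[d]))
    pos <- matrix(pos, z, n); vel <- matrix(vel, z, n)
    structure(list(positions = pos, velocities = vel,
                   pbest_pos = pos, pbest_fit = rep(NA_real_, z),
                   gbest_pos = rep(NA_real_, n), gbest_fit = NA_real_,
                   iter = 0L),
              class = "swarm_state")
  })
}

#' Minimize a function by particle swarm
#'
#' Velocity update `V <- w V + c1 r1 (pbest - H) + c2 r2 (gbest - H)` and
#' position update `H <- H + V`, with `r1`, `r2` drawn uniform on `[0, 1]`
#' per particle and dimension. Velocities are clamped to the box width;
#' positions are clipped to the box and the clipped velocity component is
#' zeroed. Minimization convention; wrap with negation to maximize.
#'
#' @param objective function of a length-`dims` numeric vector returning a
#'   finite scalar.
#' @param config a [swarm_config()].
#' @return A `pso_result` list: `par` (best position), `value` (best
#'   fitness), `history` (gbest fitness per iteration, monotone
#'   non-increasing), `config`, `n_evals`.
#' @examples
#' res <- pso_minimize(function(x) sum((x - 3)^2),
#'                     swarm_config(dims = 1, lower = 0, upper = 10,
#'                                  max_iters = 50, seed = 1))
#' res$par
#' @export
pso_minimize <- function(objective, config) {
  if (!inherits(config, "swarm_config")) abort("`config` must be a swarm_config.")
  state <- init_swarm(config)
  z <- config$n_particles; n <- config$dims
  vmax <- config$upper - config$lower
  evaluate <- function(pos) {
    f <- vapply(seq_len(z), function(i) objective(pos[i, ]), numeric(1))
    bad <- which(!is.finite(f))
    if (length(bad)) {
      abort(sprintf("Objective returned a non-finite value at position (%s).",
                    paste(signif(pos[bad[1], ], 6), collapse = ", ")))
    }
    f
  }
  withr::with_seed(derive_seed(config$seed, "updates"), {
    fit <- evaluate(state$positions)
    state$pbest_fit <- fit
    g <- which.min(fit)
    state$gbest_pos <- state$positions[g, ]
    state$gbest_fit <- fit[g]
    history <- numeric(config$max_iters + 1)
    history[1] <- state$gbest_fit
    n_evals <- z
    for (t in seq_len(config$max_iters)) {
      w <- if (is.null(config$inertia_end)) config$inertia else {
        config$inertia + (config$inertia_end - config$inertia) *
          (t - 1) / max(config$max_iters - 1, 1)
      }
      r1 <- matrix(runif(z * n), z, n)
      r2 <- matrix(runif(z * n), z, n)
      gmat <- matrix(state$gbest_pos, z, n, byrow = TRUE)
      vel <- w * state$velocities +
        config$c1 * r1 * (state$pbest_pos - state$positions) +
        config$c2 * r2 * (gmat - state$positions)
      vel <- pmin(pmax(vel, matrix(-vmax, z, n, byrow = TRUE)),
                  matrix(vmax, z, n, byrow = TRUE))
      pos <- state$positions + vel
      lo <- matrix(config$lower, z, n, byrow = TRUE)
      hi <- matrix(config$upper, z, n, byrow = TRUE)
      clipped <- pos < lo | pos > hi
      pos <- pmin(pmax(pos, lo), hi)
      vel[clipped] <- 0
      state$positions <- pos
      state$velocities <- vel
      fit <- evaluate(pos)
      n_evals <- n_evals + z
      better <- fit < state$pbest_fit
      state$pbest_fit[better] <- fit[better]
      state$pbest_pos[better, ] <- pos[better, , drop = FALSE]
      g <- which.min(state$pbest_fit)
      if (state$pbest_fit[g] < state$gbest_fit) {
        state$gbest_fit <- state$pbest_fit[g]
        state$gbest_pos <- state$pbest_pos[g, ]
      }
      history[t + 1] <- state$gbest_fit
      state$iter <- t
    }
    structure(list(par = state$gbest_pos, value = state$gbest_fit,
                   history = history, config = config, n_evals = n_evals),
              class = "pso_result")
  })
}
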