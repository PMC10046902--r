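#' Swarm configuration
#'
#' Holds every tunable of the particle swarm optimizer. The first four
#' defaults (swarm size 15, 30,000 iterations, change threshold 1e-6,
#' initialization range 1.0) are the tool's published defaults. The swarm
#' constants w, c1, c2 are not published for this tool, so canonical PSO
#' settings are used: inertia decaying linearly from `w_start` to `w_end`
#' over `max_iterations`, and local/global weights c1 = c2 = 2.0; all are
#' exposed so other values can be substituted.
#'
#' @param swarm_size Number of particles (`ss`), default 15.
#' @param max_iterations Iteration cap (`itt`), default 30000.
#' @param threshold Change-threshold exit condition: stop when the decrease
#'   of the global best score over a `patience`-iteration window falls
#'   below this value. Default 1e-6.
#' @param rand_range Bound of the uniform initial coordinate distribution
#'   (`randRange`): coordinates start in \[-rand_range, +rand_range\].
#'   Default 1.0.
#' @param w_start,w_end Inertia weight schedule endpoints (defaults 0.9 and
#'   0.4).
#' @param c1,c2 Local (personal-best) and global (swarm-best) attraction
#'   weights, defaults 2.0.
#' @param clamp_velocity Clamp each velocity component to
#'   \[-rand_range, +rand_range\] (standard divergence safeguard); default
#'   TRUE.
#' @param patience Window length, in iterations, of the change-threshold
#'   stop rule; default 500. Swarm improvement arrives in bursts, so the
#'   window must be long enough that an idle stretch during normal search
#'   is not mistaken for convergence.
#' @param seed Integer RNG seed, or NULL to use the ambient RNG state.
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(swarm_size = 15L, max_iterations = 30000L,
                         threshold = 1e-6, rand_range = 1.0,
                         w_start = 0.9, w_end = 0.4,
                         c1 = 2.0, c2 = 2.0,
                         clamp_velocity = TRUE, patience = 500L,
                         seed = NULL) {
  if (swarm_size < 1L) stop("swarm_size must be >= 1")
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  if (threshold <= 0) stop("threshold must be > 0")
  if (rand_range <= 0) stop("rand_range must be > 0")
  if (w_start < 0 || w_end < 0 || c1 < 0 || c2 < 0) {
    stop("w, c1, c2 must be nonnegative")
  }
  if (patience < 1L) stop("patience must be >= 1")
  structure(
    list(swarm_size = as.integer(swarm_size),
         max_iterations = as.integer(max_iterations),
         threshold = threshold, rand_range = rand_range,
         w_start = w_start, w_end = w_end, c1 = c1, c2 = c2,
         clamp_velocity = isTRUE(clamp_velocity),
         patience = as.integer(patience),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "swarm_config"
  )
}

# inertia weight at a given (0-based) iteration: linear decay over the run
inertia_at <- function(config, iteration) {
  frac <- min(iteration / config$max_iterations, 1)
  config$w_start - (config$w_start - config$w_end) * frac
}

# score every particle slab of a (N, 3, ss) array against the flat targets
score_particles <- function(positions, pairs, spec) {
  ss <- dim(positions)[3L]
  scores <- numeric(ss)
  for (k in seq_len(ss)) {
    scores[k] <- loss_from_residuals(
      pair_residuals(positions[, , k], pairs), spec)
  }
  scores
}

#' Initialize a particle swarm
#'
#' Every particle's coordinates are drawn independently and uniformly in
#' \[-rand_range, +rand_range\]; velocities start at zero; each particle's
#' personal best is its initial state; the global best is the minimum-loss
#' particle. Deterministic given `config$seed`.
#'
#' @param n_bins Number of chromatin bins (>= 2).
#' @param config A [swarm_config()].
#' @param targets A `distance_targets` object from [if_to_distance()].
#' @param spec A [loss_spec()].
#' @return An object of class `swarm_state`: positions, velocities and
#'   personal bests as (n_bins, 3, swarm_size) arrays, personal-best
#'   scores, the global best structure and score, and the iteration count.
#' @export
initialize_swarm <- function(n_bins, config, targets, spec = loss_spec()) {
  if (n_bins < 2L) {
    stop("a structure needs at least 2 bins (1 bin has no pairs)")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  ss <- config$swarm_size
  dims <- c(n_bins, 3L, ss)
  positions <- array(
    stats::runif(prod(dims), -config$rand_range, config$rand_range),
    dim = dims)
  pairs <- target_pairs(targets)
  scores <- score_particles(positions, pairs, spec)
  g <- which.min(scores)
  structure(
    list(positions = positions,
         velocities = array(0, dim = dims),
         best_positions = positions,
         best_scores = scores,
         gbest_positions = positions[, , g],
         gbest_score = scores[g],
         iteration = 0L,
         n_bins = as.integer(n_bins)),
    class = "swarm_state"
  )
}

#' Advance the swarm by one iteration
#'
#' Applies the canonical PSO velocity and position updates to every
#' coordinate cell of every particle:
#' V <- w V + c1 R1 (personal_best - P) + c2 R2 (global_best - P), then
#' P <- P + V, with R1 and R2 fresh uniform \[0, 1\] draws per cell. Losses
#' are re-evaluated; a personal best is replaced only on strict
#' improvement, and the global best only when some personal best strictly
#' improves it.
#'
#' @param state A `swarm_state`.
#' @param targets A `distance_targets` object.
#' @param spec A [loss_spec()].
#' @param config A [swarm_config()].
#' @param r1,r2 Optional (n_bins, 3, swarm_size) arrays of the uniform
#'   draws, for deterministic single-step checks; drawn from the RNG when
#'   NULL (R1 first, then R2).
#' @return The updated `swarm_state`.
#' @export
pso_step <- function(state, targets, spec, config, r1 = NULL, r2 = NULL) {
  dims <- dim(state$positions)
  if (is.null(r1)) r1 <- array(stats::runif(prod(dims)), dim = dims)
  if (is.null(r2)) r2 <- array(stats::runif(prod(dims)), dim = dims)
  w <- inertia_at(config, state$iteration)
  gb <- array(state$gbest_positions, dim = dims)
  v <- w * state$velocities +
    config$c1 * r1 * (state$best_positions - state$positions) +
    config$c2 * r2 * (gb - state$positions)
  if (config$clamp_velocity) {
    v <- pmin(pmax(v, -config$rand_range), config$rand_range)
  }
  p <- state$positions + v
  pairs <- target_pairs(targets)
  scores <- score_particles(p, pairs, spec)
  improved <- scores < state$best_scores
  if (any(improved)) {
    state$best_positions[, , improved] <- p[, , improved]
    state$best_scores[improved] <- scores[improved]
    g <- which.min(state$best_scores)
    if (state$best_scores[g] < state$gbest_score) {
      state$gbest_score <- state$best_scores[g]
      state$gbest_positions <- state$best_positions[, , g]
    }
  }
  state$positions <- p
  state$velocities <- v
  state$iteration <- state$iteration + 1L
  state
}

#' Reconstruct a 3D structure from a contact matrix by PSO
#'
#' Converts the interaction frequencies to expected distances at the given
#' beta, then iterates the swarm until `max_iterations` is reached or the
#' decrease of the global best score over a `patience`-iteration window
#' falls below `threshold`. The global best score is non-increasing by
#' construction.
#'
#' @param matrix A [contact_matrix()].
#' @param config A [swarm_config()].
#' @param spec A [loss_spec()].
#' @param beta Positive conversion-factor exponent (default 1.0).
#' @param unit_scale Passed to [if_to_distance()].
#' @return An object of class `chromo_structure`: list with `positions`
#'   (N x 3 global best), `bin_labels`, `evaluation` (an
#'   `evaluation_record`), `provenance` (beta, loss, seed, iterations used,
#'   stop reason, config) and `trace` (global best score per iteration).
#' @export
pso_run <- function(matrix, config = swarm_config(), spec = loss_spec(),
                    beta = 1.0, unit_scale = 1.0) {
  stopifnot(inherits(matrix, "contact_matrix"))
  targets <- if_to_distance(matrix, beta, unit_scale)
  state <- initialize_swarm(matrix$n_bins, config, targets, spec)
  trace <- numeric(config$max_iterations)
  window_anchor <- state$gbest_score
  stop_reason <- "max_iterations"
  iterations <- config$max_iterations
  for (it in seq_len(config$max_iterations)) {
    state <- pso_step(state, targets, spec, config)
    trace[it] <- state$gbest_score
    if (it %% config$patience == 0L) {
      if (window_anchor - state$gbest_score < config$threshold) {
        stop_reason <- "threshold"
        iterations <- it
        break
      }
      window_anchor <- state$gbest_score
    }
  }
  eval_rec <- evaluate_structure(state$gbest_positions, targets, spec)
  structure(
    list(positions = state$gbest_positions,
         bin_labels = matrix$bin_labels,
         evaluation = eval_rec,
         targets = targets,
         provenance = list(beta = beta, loss_name = spec$name,
                           alpha = spec$alpha, seed = config$seed,
                           iterations = iterations,
                           stop_reason = stop_reason,
                           config = config),
         trace = trace[seq_len(iterations)]),
    class = "chromo_structure"
  )
}

#' @export
print.chromo_structure <- function(x, ...) {
  cat(sprintf(
    "<chromo_structure> %d bins | beta %g | %s after %d iterations\n",
    nrow(x$positions), x$provenance$beta, x$provenance$stop_reason,
    x$provenance$iterations))
  print(x$evaluation)
  invisible(x)
}
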