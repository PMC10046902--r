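quick_targets <- function(n_bins = 8L) {
  if_to_distance(helix_fixture(n_bins)$if_matrix, beta = 1.0)
}

test_that("swarm initialization respects bounds, seeds, and bookkeeping", {
  tg <- quick_targets()
  cfg <- swarm_config(swarm_size = 5L, seed = 9L, rand_range = 1.0)
  st <- initialize_swarm(8L, cfg, tg, loss_spec())

  expect_equal(dim(st$positions), c(8L, 3L, 5L))
  expect_true(all(st$velocities == 0))
  expect_identical(st$best_positions, st$positions)
  expect_equal(st$gbest_score, min(st$best_scores))
  expect_equal(st$iteration, 0L)

  # same seed -> bit-identical state
  st2 <- initialize_swarm(8L, cfg, tg, loss_spec())
  expect_identical(st, st2)

  # single-particle swarm: global best is that particle
  one <- initialize_swarm(8L, swarm_config(swarm_size = 1L, seed = 2L),
                          tg, loss_spec())
  expect_equal(one$gbest_score, one$best_scores[1L])

  # coordinate bounds over many draws
  big <- initialize_swarm(
    8L, swarm_config(swarm_size = 50L, seed = 3L, rand_range = 1.0),
    tg, loss_spec())
  expect_gte(min(big$positions), -1)
  expect_lte(max(big$positions), 1)

  expect_error(initialize_swarm(1L, cfg, tg, loss_spec()), "at least 2")
})

test_that("a single update cell matches the hand-computed PSO equations", {
  # P=0, V=1, personal best=2, global best=3, w=0.5, c1=c2=1,
  # R1=0.25, R2=0.5 -> V' = 0.5 + 0.25*2 + 0.5*3 = 2.5, P' = 2.5
  tg <- quick_targets(2L + 6L)  # 8 bins
  cfg <- swarm_config(swarm_size = 1L, seed = 1L, w_start = 0.5,
                      w_end = 0.5, c1 = 1, c2 = 1,
                      clamp_velocity = FALSE)
  st <- initialize_swarm(8L, cfg, tg, loss_spec())
  st$positions[] <- 0
  st$velocities[] <- 1
  st$best_positions[] <- 2
  st$gbest_positions <- matrix(3, 8L, 3L)
  st$best_scores[] <- Inf
  st$gbest_score <- Inf
  dims <- dim(st$positions)
  r1 <- array(0.25, dims)
  r2 <- array(0.5, dims)
  out <- pso_step(st, tg, loss_spec(), cfg, r1 = r1, r2 = r2)
  expect_equal(out$velocities, array(2.5, dims))
  expect_equal(out$positions, array(2.5, dims))
  expect_equal(out$iteration, 1L)
})

test_that("all-zero coefficients freeze the swarm", {
  tg <- quick_targets()
  cfg <- swarm_config(swarm_size = 4L, seed = 5L, w_start = 0, w_end = 0,
                      c1 = 0, c2 = 0)
  st <- initialize_swarm(8L, cfg, tg, loss_spec())
  out <- pso_step(st, tg, loss_spec(), cfg)
  expect_equal(out$positions, st$positions)
  expect_true(all(out$velocities == 0))
  expect_equal(out$best_scores, st$best_scores)
  expect_equal(out$gbest_score, st$gbest_score)
})

test_that("a particle sitting at both bests keeps only its inertia term", {
  tg <- quick_targets()
  cfg <- swarm_config(swarm_size = 1L, seed = 8L, w_start = 0.5,
                      w_end = 0.5, c1 = 1, c2 = 1, clamp_velocity = FALSE)
  st <- initialize_swarm(8L, cfg, tg, loss_spec())
  st$best_positions <- st$positions
  st$gbest_positions <- st$positions[, , 1L]
  st$velocities[] <- 0.2
  out <- pso_step(st, tg, loss_spec(), cfg)
  expect_equal(out$velocities, 0.5 * st$velocities)
})

test_that("with c1=c2=0 and w<1 velocities decay geometrically", {
  tg <- quick_targets()
  cfg <- swarm_config(swarm_size = 2L, seed = 4L, w_start = 0.5,
                      w_end = 0.5, c1 = 0, c2 = 0)
  st <- initialize_swarm(8L, cfg, tg, loss_spec())
  st$velocities[] <- 0.8
  for (k in 1:5) st <- pso_step(st, tg, loss_spec(), cfg)
  expect_equal(max(abs(st$velocities)), 0.8 * 0.5^5, tolerance = 1e-12)
})

test_that("global best score is non-increasing over thousands of steps", {
  fx <- helix_fixture(10L)
  st <- pso_run(fx$if_matrix,
                swarm_config(max_iterations = 5000L, seed = 11L,
                             threshold = 1e-14))
  expect_true(all(diff(st$trace) <= 0))
})

test_that("runs are bit-reproducible under the same seed", {
  fx <- helix_fixture(10L)
  cfg <- swarm_config(max_iterations = 300L, seed = 21L)
  a <- pso_run(fx$if_matrix, cfg)
  b <- pso_run(fx$if_matrix, cfg)
  expect_identical(a$positions, b$positions)
  expect_identical(a$evaluation$scc, b$evaluation$scc)
  expect_identical(a$trace, b$trace)
})

test_that("stop conditions report the right reason", {
  fx <- helix_fixture(8L)
  one <- pso_run(fx$if_matrix,
                 swarm_config(max_iterations = 1L, seed = 1L))
  expect_equal(one$provenance$iterations, 1L)
  expect_equal(one$provenance$stop_reason, "max_iterations")

  early <- pso_run(fx$if_matrix,
                   swarm_config(max_iterations = 10000L, seed = 1L,
                                threshold = 1e9, patience = 50L))
  expect_equal(early$provenance$stop_reason, "threshold")
  expect_equal(early$provenance$iterations, 50L)
})

test_that("rescaling the IF matrix leaves the run unchanged at fixed seed", {
  fx <- helix_fixture(10L)
  cfg <- swarm_config(max_iterations = 400L, seed = 31L)
  a <- pso_run(fx$if_matrix, cfg)
  scaled <- contact_matrix(fx$if_matrix$values * 7.5)
  b <- pso_run(scaled, cfg)
  expect_identical(a$evaluation$scc, b$evaluation$scc)
  expect_identical(a$positions, b$positions)
})

test_that("noiseless helix is recovered within a reduced budget", {
  fx <- helix_fixture(20L)
  st <- pso_run(fx$if_matrix,
                swarm_config(max_iterations = 5000L, seed = 42L))
  expect_gte(st$evaluation$scc, 0.9)
  expect_gte(st$evaluation$pcc, 0.9)
})

test_that("swarm_config validates its fields", {
  expect_error(swarm_config(swarm_size = 0L), "swarm_size")
  expect_error(swarm_config(max_iterations = 0L), "max_iterations")
  expect_error(swarm_config(threshold = 0), "threshold")
  expect_error(swarm_config(rand_range = -1), "rand_range")
  expect_error(swarm_config(c1 = -0.1), "nonnegative")
})
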