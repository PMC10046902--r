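#' Generate a ground-truth 3D curve
#'
#' Parametric test structures for validating the full reconstruction
#' pipeline without any external data: a helix, a circle, or a seeded
#' random walk with unit steps that resamples steps landing too close to
#' previously placed beads. All pairwise distances are strictly positive.
#'
#' @param kind One of `"helix"`, `"circle"`, `"random_walk"`.
#' @param n_bins Number of beads (>= 2).
#' @param seed Integer seed; only the random walk consumes randomness, but
#'   the argument is accepted for every kind so callers can treat
#'   generators uniformly.
#' @return N x 3 coordinate matrix.
#' @export
make_structure <- function(kind = c("helix", "random_walk", "circle"),
                           n_bins, seed = 1L) {
  kind <- match.arg(kind)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  switch(kind,
    helix = {
      t <- seq_len(n_bins) - 1L
      theta <- t * (2 * pi / 10)  # 10 beads per turn
      cbind(cos(theta), sin(theta), 0.2 * t)
    },
    circle = {
      theta <- (seq_len(n_bins) - 1L) * (2 * pi / n_bins)
      cbind(cos(theta), sin(theta), 0)
    },
    random_walk = {
      set.seed(seed)
      pos <- matrix(0, n_bins, 3L)
      for (b in 2:n_bins) {
        for (try in 1:50) {
          u <- stats::rnorm(3L)
          step <- u / sqrt(sum(u^2))
          cand <- pos[b - 1L, ] + step
          d <- sqrt(rowSums((pos[seq_len(b - 1L), , drop = FALSE] -
                               matrix(cand, b - 1L, 3L, byrow = TRUE))^2))
          if (all(d > 0.5)) break
        }
        pos[b, ] <- cand
      }
      pos
    }
  )
}

#' Derive the interaction-frequency matrix a structure implies
#'
#' Inverts the distance conversion D = 1/IF^beta: each pair's interaction
#' frequency is IF = (1 / distance)^(1/beta), so converting the result
#' back with the same beta recovers the true distances up to one common
#' scale factor. Optional multiplicative log-normal noise (symmetric per
#' pair) emulates measurement scatter while keeping IF positive.
#'
#' @param positions N x 3 matrix with all pairwise distances > 0.
#' @param beta Positive conversion factor used for the inversion.
#' @param noise_sd Standard deviation of the Gaussian noise on log IF
#'   (default 0 = noiseless).
#' @param seed Integer seed for the noise draws.
#' @return A [contact_matrix()] with zero diagonal.
#' @export
structure_to_if <- function(positions, beta = 1.0, noise_sd = 0,
                            seed = 1L) {
  positions <- as.matrix(positions)
  if (beta <= 0) stop("beta must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  d <- as.matrix(stats::dist(positions))
  n <- nrow(d)
  off <- upper.tri(d)
  if (any(d[off] == 0)) {
    stop("coincident bins: zero pairwise distance implies infinite IF")
  }
  m <- matrix(0, n, n)
  if_upper <- (1 / d[off])^(1 / beta)
  if (noise_sd > 0) {
    set.seed(seed)
    if_upper <- if_upper * exp(stats::rnorm(length(if_upper), 0, noise_sd))
  }
  m[off] <- if_upper
  m <- m + t(m)
  contact_matrix(m)
}

#' Build a complete synthetic fixture
#'
#' Bundles a ground-truth structure with the IF matrix it implies, so
#' every downstream module (conversion, optimization, evaluation, output)
#' can be exercised against a known answer.
#'
#' @inheritParams make_structure
#' @inheritParams structure_to_if
#' @param beta_true Conversion factor used to generate the IF matrix.
#' @return List with `true_positions`, `if_matrix`, `beta_true`,
#'   `noise_sd`.
#' @export
make_fixture <- function(kind = "helix", n_bins = 20L, beta_true = 1.0,
                         noise_sd = 0, seed = 1L) {
  pos <- make_structure(kind, n_bins, seed)
  list(true_positions = pos,
       if_matrix = structure_to_if(pos, beta_true, noise_sd, seed),
       beta_true = beta_true,
       noise_sd = noise_sd)
}
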