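#' Convert interaction frequencies to expected pairwise distances
#'
#' Implements the distance-method conversion D = 1 / IF^beta between
#' contact frequency and expected spatial separation: frequently contacting
#' bins are expected to lie close together. Pairs with IF = 0 carry no
#' distance information and are excluded via the mask, as is the diagonal.
#' Because the conversion is scale-free, the masked distances are rescaled
#' by a common positive factor so that the largest expected distance equals
#' `unit_scale`; this puts the targets on the same scale as the particle
#' initialization range.
#'
#' @param matrix A [contact_matrix()].
#' @param beta Positive conversion-factor exponent.
#' @param unit_scale Positive scale that the maximum masked distance is
#'   mapped to (default 1.0, matching the default initialization range).
#' @return An object of class `distance_targets`: list with `n_bins`,
#'   `d_expected` (N x N, `NA` on unmasked cells), `mask` (N x N logical),
#'   `beta`, and `scale_factor` (the common factor applied).
#' @export
if_to_distance <- function(matrix, beta, unit_scale = 1.0) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop("beta must be a single positive number")
  }
  if (!is.numeric(unit_scale) || length(unit_scale) != 1L || unit_scale <= 0) {
    stop("unit_scale must be a single positive number")
  }
  v <- matrix$values
  n <- matrix$n_bins
  mask <- v > 0
  diag(mask) <- FALSE
  if (!any(mask)) {
    stop("no pair has positive interaction frequency; nothing to convert")
  }
  d <- base::matrix(NA_real_, n, n)
  d[mask] <- 1 / (v[mask]^beta)
  scale_factor <- unit_scale / max(d[mask])
  d[mask] <- d[mask] * scale_factor
  structure(
    list(n_bins = n, d_expected = d, mask = mask, beta = beta,
         scale_factor = scale_factor),
    class = "distance_targets"
  )
}

#' @export
print.distance_targets <- function(x, ...) {
  cat(sprintf(
    "<distance_targets> %d bins, %d masked pairs, beta = %g\n",
    x$n_bins, sum(x$mask[upper.tri(x$mask)]), x$beta))
  invisible(x)
}

# masked unordered pair indices (i < j) and their expected distances,
# the flat form the optimizer and evaluator work on
target_pairs <- function(targets) {
  ut <- upper.tri(targets$mask) & targets$mask
  idx <- which(ut, arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L], d = targets$d_expected[ut])
}

#' Select the conversion factor beta by grid search
#'
#' Runs the full reconstruction at each candidate beta and returns the beta
#' whose final structure attains the highest Spearman correlation between
#' realized and expected distances. Ties are broken toward the smaller
#' beta. Each candidate run uses the same seed so candidates differ only in
#' their distance targets.
#'
#' @param matrix A [contact_matrix()].
#' @param candidates Ordered vector of positive candidate betas; default
#'   grid 0.1 to 1.5 in steps of 0.1.
#' @param config A [swarm_config()] used for every candidate run.
#' @param spec A [loss_spec()].
#' @return List with `best_beta`, `best_structure`, and `scores`, a
#'   data.frame of (beta, scc) over the grid.
#' @export
search_beta <- function(matrix, candidates = seq(0.1, 1.5, by = 0.1),
                        config = swarm_config(), spec = loss_spec()) {
  if (length(candidates) == 0L) {
    stop("candidate list for beta search is empty")
  }
  if (any(candidates <= 0)) {
    stop("all beta candidates must be positive")
  }
  structures <- vector("list", length(candidates))
  scc <- numeric(length(candidates))
  for (k in seq_along(candidates)) {
    structures[[k]] <- pso_run(matrix, config = config, spec = spec,
                               beta = candidates[k])
    scc[k] <- structures[[k]]$evaluation$scc
  }
  # highest SCC; ties toward the smaller beta
  ord <- order(-scc, candidates)
  best <- ord[1L]
  list(best_beta = candidates[best],
       best_structure = structures[[best]],
       scores = data.frame(beta = candidates, scc = scc))
}
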