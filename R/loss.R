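#' Loss function specification
#'
#' Four selectable losses score a candidate structure's realized pairwise
#' distances d against the expected distances D, over masked unordered
#' pairs: RMSE, MSE, SSE, and the Huber loss with threshold `alpha`. The
#' integer selector mirrors the tool's `lf` parameter, in the order the
#' losses are listed: 0 = RMSE, 1 = MSE, 2 = SSE, 3 = Huber.
#'
#' @param selector Integer in 0..3, or one of `"rmse"`, `"mse"`, `"sse"`,
#'   `"huber"`.
#' @param alpha Positive Huber threshold; default 0.5.
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(selector = 0L, alpha = 0.5) {
  names <- c("rmse", "mse", "sse", "huber")
  if (is.character(selector)) {
    selector <- match(tolower(selector), names) - 1L
    if (is.na(selector)) {
      stop("unknown loss name; use rmse, mse, sse, or huber")
    }
  }
  if (length(selector) != 1L || is.na(selector) ||
      selector != floor(selector) || selector < 0 || selector > 3) {
    stop("loss selector must be an integer in [0, 3]")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a single positive number")
  }
  structure(
    list(selector = as.integer(selector), name = names[selector + 1L],
         alpha = alpha),
    class = "loss_spec"
  )
}

#' Pairwise Euclidean distances of a structure
#'
#' @param positions N x 3 matrix of finite bead coordinates.
#' @return Symmetric N x N matrix of Euclidean distances, zero diagonal.
#' @export
realized_distances <- function(positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) {
    stop("positions must be an N x 3 matrix")
  }
  if (anyNA(positions) || any(!is.finite(positions))) {
    stop("positions contain non-finite coordinates")
  }
  as.matrix(stats::dist(positions))
}

# residuals d - D over masked pairs, from flat pair form (internal hot path)
pair_residuals <- function(positions, pairs) {
  dx <- positions[pairs$i, , drop = FALSE] - positions[pairs$j, , drop = FALSE]
  sqrt(rowSums(dx * dx)) - pairs$d
}

# loss from a residual vector; ncount = number of masked unordered pairs
loss_from_residuals <- function(residuals, spec) {
  sq <- residuals^2
  switch(spec$name,
    rmse = sqrt(mean(sq)),
    mse = mean(sq),
    sse = sum(sq),
    huber = {
      a <- spec$alpha
      abs_r <- abs(residuals)
      mean(ifelse(abs_r <= a, 0.5 * sq, a * (abs_r - 0.5 * a)))
    }
  )
}

#' Score realized distances against expected distances
#'
#' Computed over masked unordered pairs (i < j) only. With residuals
#' r = d - D and ncount the number of masked pairs:
#' MSE = mean(r^2), RMSE = sqrt(MSE), SSE = sum(r^2), and Huber the mean of
#' the standard piecewise form (r^2/2 when |r| <= alpha, else
#' alpha(|r| - alpha/2)).
#'
#' @param d N x N realized-distance matrix (e.g. from
#'   [realized_distances()]).
#' @param targets A `distance_targets` object from [if_to_distance()].
#' @param spec A [loss_spec()].
#' @return A single nonnegative number; zero exactly when every masked
#'   realized distance equals its target.
#' @export
loss_value <- function(d, targets, spec = loss_spec()) {
  stopifnot(inherits(targets, "distance_targets"), inherits(spec, "loss_spec"))
  d <- as.matrix(d)
  if (nrow(d) != targets$n_bins || ncol(d) != targets$n_bins) {
    stop("realized distances and targets disagree on the number of bins")
  }
  ut <- upper.tri(targets$mask) & targets$mask
  if (!any(ut)) {
    stop("no comparable pairs: every pair is unmasked")
  }
  loss_from_residuals(d[ut] - targets$d_expected[ut], spec)
}
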