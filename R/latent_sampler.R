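#' Latent-space scale
#'
#' A scalar summary of the spread of the encoded training data: the
#' root-mean-square distance of the latent points about their centroid.
#' `L` is zero for a degenerate (single-point) latent cloud and scales
#' linearly when the cloud is dilated about its centroid; its stability
#' across the loss ratio `lambda` identifies the usable `lambda` region.
#'
#' @param z N-by-d matrix of latent points (post-training, `z = mu`).
#' @return Scalar `L >= 0`.
#' @export
latent_scale <- function(z) {
  z <- rbind(z)
  if (nrow(z) < 1) abort("at least one latent point is required")
  centroid <- colMeans(z)
  sqrt(mean(rowSums(sweep(z, 2, centroid)^2)))
}

#' Extended sampling rectangle over the latent data
#'
#' The minimal axis-aligned bounding box of the latent points, each side
#' length multiplied by `1 + rate` symmetrically about the box center.  A
#' 20% expansion balances sampling known latent areas against exploring
#' beyond the data.  Collapsed (zero-width) sides are opened by an absolute
#' 0.1 on each end so sampling never degenerates to a point.
#'
#' @param z N-by-d matrix of latent points.
#' @param rate Expansion rate; default 0.2 (20%).
#' @return A `sampling_rectangle`: list with `lower` and `upper` d-vectors.
#' @export
make_rectangle <- function(z, rate = 0.2) {
  z <- rbind(z)
  if (nrow(z) < 1) abort("empty point set")
  lo <- apply(z, 2, min)
  hi <- apply(z, 2, max)
  center <- (lo + hi) / 2
  half <- (hi - lo) / 2 * (1 + rate)
  collapsed <- (hi - lo) == 0
  half[collapsed] <- 0.1
  structure(list(lower = center - half, upper = center + half),
            class = "sampling_rectangle")
}

#' Draw a uniform batch from a sampling rectangle
#'
#' @param rect A [make_rectangle()] result.
#' @param batch_size Number of points; the production default per iteration
#'   is 50.
#' @param seed Optional integer seed.
#' @return batch_size-by-d matrix of i.i.d. uniform latent points.
#' @export
draw_batch <- function(rect, batch_size = 50, seed = NULL) {
  d <- length(rect$lower)
  draw <- function() {
    u <- matrix(stats::runif(batch_size * d), batch_size, d)
    sweep(sweep(u, 2, rect$upper - rect$lower, "*"), 2, rect$lower, "+")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
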