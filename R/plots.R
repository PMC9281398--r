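#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_segment
#'   geom_raster labs theme_minimal scale_color_viridis_c
#' @export
ggplot2::autoplot

#' Plot the VAE training history
#'
#' @param object A trained `lols_vae`.
#' @param ... Unused.
#' @return A ggplot: per-epoch reconstruction, KL and total loss.
#' @method autoplot lols_vae
#' @export
autoplot.lols_vae <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("rec", "kld", "total"),
                           names_to = "term", values_to = "loss")
  ggplot(h, aes(x = .data$epoch, y = .data$loss, color = .data$term)) +
    geom_line() +
    labs(x = "epoch", y = "loss", color = NULL,
         title = "VAE training history") +
    theme_minimal()
}

#' Plot latent-space snapshots of a run
#'
#' @param run An `lols_run` with latent snapshots.
#' @param iteration Iteration to show; default the last one.
#' @return A ggplot: latent points colored by scaled energy.
#' @export
plot_latent <- function(run, iteration = NULL) {
  stopifnot(nrow(run$latent) > 0)
  it <- iteration %||% max(run$latent$iteration)
  d <- dplyr::filter(run$latent, .data$iteration == it)
  ggplot(d, aes(x = .data$z1, y = .data$z2, color = .data$scaled_energy)) +
    geom_point(size = 0.8) +
    scale_color_viridis_c() +
    labs(title = paste0("latent space, iteration ", it),
         x = "z1", y = "z2", color = "E*") +
    theme_minimal()
}

#' Plot a run's conformer energy ladder
#'
#' Each conformer is a horizontal level at its energy above the global
#' minimum; reference targets, when supplied, are drawn alongside.
#'
#' @param object An `lols_run`.
#' @param targets Optional reference conformer tibble with `rel_energy`.
#' @param ... Unused.
#' @method autoplot lols_run
#' @export
autoplot.lols_run <- function(object, targets = NULL, ...) {
  d <- dplyr::mutate(object$conformers, set = "found")
  if (!is.null(targets)) {
    t2 <- tibble(rel_energy = targets$rel_energy, set = "target")
    d <- dplyr::bind_rows(dplyr::select(d, "rel_energy", "set"), t2)
  }
  ggplot(d, aes(x = .data$set, y = .data$rel_energy)) +
    geom_segment(aes(x = as.integer(factor(.data$set)) - 0.3,
                     xend = as.integer(factor(.data$set)) + 0.3,
                     yend = .data$rel_energy)) +
    labs(x = NULL, y = "energy above global minimum (eV)",
         title = "conformer energy ladder") +
    theme_minimal()
}

#' Plot a latent island map
#'
#' @param object An `lols_islands` report.
#' @param ... Unused.
#' @method autoplot lols_islands
#' @export
autoplot.lols_islands <- function(object, ...) {
  d <- object$assignment
  ggplot(d, aes(x = .data$z1, y = .data$z2,
                fill = factor(.data$target))) +
    geom_raster() +
    labs(x = "z1", y = "z2", fill = "target",
         title = sprintf("latent islands (%.2f%% of area)",
                         100 * object$total_area_fraction)) +
    theme_minimal()
}
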