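#' Normalize dihedral angles to the unit interval
#'
#' Maps each dimension linearly from its declared range `[low, high]` onto
#' `[-1, 1]`; for full-range torsions this is the standard `[0, 360]` to
#' `[-1, 1]` map.  [denormalize_angles()] is the exact inverse.
#'
#' @param angles Degree vector, or matrix with one row per record.
#' @param ranges Tibble with columns `low`, `high` (and `periodic`); defaults
#'   to full 360-degree ranges.
#' @return Normalized values in `[-1, 1]` of the same shape as `angles`.
#' @export
normalize_angles <- function(angles, ranges = NULL) {
  m <- is.matrix(angles)
  D <- if (m) ncol(angles) else length(angles)
  ranges <- as_ranges(ranges, D)
  lo <- ranges$low; hi <- ranges$high
  check <- if (m) sweep(angles, 2, lo - 1e-9, ">=") & sweep(angles, 2, hi + 1e-9, "<=")
           else angles >= lo - 1e-9 & angles <= hi + 1e-9
  if (!all(check)) abort("angle outside its declared range")
  if (m) {
    sweep(sweep(angles, 2, lo), 2, (hi - lo) / 2, "/") - 1
  } else {
    2 * (angles - lo) / (hi - lo) - 1
  }
}

#' @rdname normalize_angles
#' @param x Normalized values in `[-1, 1]`.
#' @export
denormalize_angles <- function(x, ranges = NULL) {
  m <- is.matrix(x)
  D <- if (m) ncol(x) else length(x)
  ranges <- as_ranges(ranges, D)
  lo <- ranges$low; hi <- ranges$high
  if (m) {
    sweep(sweep(x + 1, 2, (hi - lo) / 2, "*"), 2, lo, "+")
  } else {
    lo + (x + 1) * (hi - lo) / 2
  }
}

#' Scale raw energies for model fitting
#'
#' Shifts energies by the per-molecule threshold `E0` and compresses the
#' high-energy tail logarithmically:
#' \deqn{E^* = \begin{cases} E - E_0 & E \le E_0 \\ \ln(1 + E - E_0) & E > E_0 \end{cases}}
#' The map is continuous, differentiable and strictly increasing, leaves
#' energies near `E0` close to zero, and guarantees that increments of
#' `E*` above `E0` never exceed the corresponding raw increments.  Because
#' the map is monotone, minima locations are identical whether the energy
#' model is fitted to `E` or to `E*`.
#'
#' @param E Raw energies in eV.
#' @param E0 Threshold energy in eV; system dependent, held constant per
#'   molecule once chosen (for synthetic backends it defaults to the minimum
#'   of the initial data).
#' @return Scaled energies `E*` (dimensionless above `E0`, eV-linear below).
#' @export
scale_energy <- function(E, E0) {
  stopifnot(is.finite(E0))
  d <- E - E0
  hi <- d > 0
  d[hi] <- log1p(d[hi])
  d
}

#' Flag high-energy records for exclusion from VAE training
#'
#' Computes the cutoff `E*_max = mean(E*) + alpha * sd(E*)` over the pool
#' (population standard deviation) and marks records with `E*` strictly
#' greater than the cutoff as excluded from the VAE training set.  Excluded
#' records stay in the pool and still feed the energy model; with the default
#' `alpha = 2` these are typically sterically strained, physically irrelevant
#' structures.
#'
#' @param pool Tibble with a `scaled_energy` column.
#' @param alpha Cutoff threshold in population standard deviations; default 2.
#' @return The pool with a (re)computed logical `vae_included` column.
#' @export
vae_cutoff <- function(pool, alpha = 2) {
  if (nrow(pool) == 0) abort("empty pool")
  es <- pool$scaled_energy
  mu <- mean(es)
  sd_pop <- sqrt(mean((es - mu)^2))
  pool$vae_included <- es <= mu + alpha * sd_pop
  pool
}

#' Assemble a data-pool tibble
#'
#' The data pool is the growing training set of the active-learning loop:
#' one row per evaluated conformation with its dihedral angles (degrees),
#' raw energy, scaled energy, VAE-inclusion flag and provenance.
#'
#' @param angles Matrix of dihedral angles (degrees), one row per record.
#' @param energy Raw energies (eV).
#' @param E0 Threshold energy used by [scale_energy()].
#' @param iteration Iteration index (0 for initial data).
#' @param run_id Run identifier.
#' @return Tibble with columns `angle_1..angle_D`, `energy_eV`,
#'   `scaled_energy`, `vae_included`, `iteration`, `run_id`.
#' @export
make_pool <- function(angles, energy, E0, iteration = 0L, run_id = 1L) {
  angles <- rbind(angles)
  colnames(angles) <- angle_cols(ncol(angles))
  dplyr::bind_cols(
    as_tibble(angles),
    tibble(energy_eV = as.numeric(energy),
           scaled_energy = scale_energy(as.numeric(energy), E0),
           vae_included = TRUE,
           iteration = as.integer(iteration),
           run_id = as.integer(run_id))
  )
}

#' Read/write the data pool as a delimited table
#'
#' @param pool Pool tibble (see [make_pool()]).
#' @param path File path (tab-separated, with header).
#' @export
write_pool <- function(pool, path) {
  readr::write_tsv(pool, path)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
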