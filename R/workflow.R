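#' Run configuration for the conformer-search loop
#'
#' Defaults follow the production settings of the method for a
#' five-dimensional search (general settings: latent dimension 2, cutoff
#' threshold alpha 2, loss ratio lambda 0.01, expansion rate 20%, batch
#' size 50, STDP kernel with fixed noise 0.001 eV; molecule-level settings
#' for a 5-D system: initial data 100, layersize 80, maximum iteration 40,
#' energy-model interval 5).
#'
#' @param initdata Initial pool size (valid records).
#' @param M Maximum number of loop iterations.
#' @param k Energy-model interval: the surrogate is fitted at iterations
#'   `k, 2k, ...` and always at `M`.
#' @param batch_size Latent samples decoded and evaluated per iteration.
#' @param alpha High-energy cutoff threshold (population SDs).
#' @param beta Energy weight of the VAE reconstruction loss (<= 0).
#' @param lambda Loss ratio between reconstruction and KL terms.
#' @param layersize Encoder/decoder hidden-layer width.
#' @param latent_dim Latent dimensionality.
#' @param expansion_rate Rectangle expansion rate for latent sampling.
#' @param E0 Threshold energy (eV) for [scale_energy()]; `NULL` uses the
#'   minimum energy of the initial data.
#' @param noise Fixed GP observation noise (eV).
#' @param epochs Per-retraining epoch budget of the in-loop VAE (plateau
#'   early stopping applies; see the methods vignette).
#' @param patience,rtol Early-stopping window and relative tolerance.
#' @param seed Base integer seed of the run.
#' @param refine_max_steps Maximum refinement steps per candidate.
#' @param refine_force_tol Gradient-norm convergence threshold for
#'   refinement (eV/degree).
#' @param warm_start Warm-start the VAE from the previous iteration instead
#'   of re-initializing; default `FALSE` (fresh seeded restart).
#' @param stop_frac Fraction of reference targets that, together with the
#'   global minimum, stops the loop early (benchmark mode only).
#' @return A `lols_config` list.
#' @export
lols_config <- function(initdata = 100, M = 40, k = 5, batch_size = 50,
                        alpha = 2, beta = -1, lambda = 0.01, layersize = 80,
                        latent_dim = 2, expansion_rate = 0.2, E0 = NULL,
                        noise = 0.001, epochs = 2000, patience = 200,
                        rtol = 1e-5, seed = 1L, refine_max_steps = 200,
                        refine_force_tol = 0.01, warm_start = FALSE,
                        stop_frac = 0.7) {
  stopifnot(M >= 1, k >= 1, batch_size >= 1, initdata >= 1, beta <= 0)
  structure(as.list(environment()), class = "lols_config")
}

#' Generate the initial data pool by uniform random sampling
#'
#' Draws conformations uniformly over the per-dimension ranges, evaluates
#' them on the backend and resamples invalid draws until `n` valid records
#' exist.  (An externally produced pool in the data-pool file format can be
#' supplied to [run_lols()] instead via `initial_pool`.)
#'
#' @param backend An `energy_backend`.
#' @param n Number of valid records required.
#' @param seed Integer seed.
#' @param E0 Threshold energy; `NULL` defers scaling to the caller.
#' @param run_id Run identifier stored in the pool.
#' @return A pool tibble with attribute `attempts` (total evaluations
#'   including invalid draws).
#' @export
generate_initial_data <- function(backend, n, seed = 1L, E0 = NULL,
                                  run_id = 1L) {
  ranges <- backend$ranges
  D <- backend$dim
  angles <- matrix(numeric(0), 0, D)
  energies <- numeric(0)
  attempts <- 0L
  withr::with_seed(as.integer(seed), {
    while (nrow(angles) < n) {
      miss <- n - nrow(angles)
      draw <- matrix(stats::runif(miss * D), miss, D)
      draw <- sweep(sweep(draw, 2, ranges$high - ranges$low, "*"), 2,
                    ranges$low, "+")
      E <- evaluate_energy(backend, draw)
      attempts <- attempts + miss
      ok <- !is.na(E)
      angles <- rbind(angles, draw[ok, , drop = FALSE])
      energies <- c(energies, E[ok])
    }
  })
  if (is.null(E0)) E0 <- min(energies)
  pool <- make_pool(angles, energies, E0, iteration = 0L, run_id = run_id)
  attr(pool, "attempts") <- attempts
  attr(pool, "E0") <- E0
  pool
}

# Fit the surrogate on the full pool and bank its merged local minima.
bank_minima <- function(pool, ranges, noise, iteration, run_id) {
  gp <- fit_energy_model(pool, ranges = ranges, noise = noise)
  mins <- extract_local_minima(gp)
  mins <- merge_similar(mins, ranges = ranges)
  if (nrow(mins)) {
    mins$model_index <- iteration
    mins$run_id <- run_id
  }
  list(gp = gp, minima = mins)
}

#' Run one seeded active-learning conformer search
#'
#' Implements the data-generation loop: at every iteration the pool is
#' preprocessed (normalization, energy scaling, alpha cutoff), the
#' energy-weighted VAE is retrained on the included records, the pool is
#' encoded, a batch of latent points is drawn from the 20%-expanded
#' bounding rectangle, decoded, evaluated on the backend and appended to
#' the pool.  Every `k` iterations (and at `M`) the periodic-kernel GP is
#' fitted to the full pool and its local minima are banked; candidates from
#' every energy model are retained because minima can transiently disappear
#' between refits.  After the loop all banked candidates are refined on the
#' true backend energy, non-converged candidates are dropped, and the
#' survivors are deduplicated and ranked.
#'
#' @param backend An `energy_backend`.
#' @param config An [lols_config()].
#' @param targets Optional reference conformer tibble (`angle_*`, `energy`,
#'   `rel_energy`): enables the early-stopping rule (global minimum found
#'   and at least `stop_frac` of targets reached) and the per-iteration
#'   achievement curve.
#' @param run_id Integer run identifier.
#' @param initial_pool Optional externally produced pool tibble replacing
#'   uniform initialization.
#' @return An `lols_run` object: `conformers` (refined, deduplicated,
#'   ranked), `pool`, `bank` (unrefined candidates per energy model),
#'   `latent` (per-iteration latent snapshots), `curve`, `counts`
#'   (single-point/relax/converged bookkeeping), `invalid`, `E0`.
#' @export
run_lols <- function(backend, config = lols_config(), targets = NULL,
                     run_id = 1L, initial_pool = NULL) {
  ranges <- backend$ranges
  D <- backend$dim
  seed <- as.integer(config$seed)

  if (is.null(initial_pool)) {
    pool <- generate_initial_data(backend, config$initdata, seed = seed,
                                  E0 = config$E0, run_id = run_id)
    attempts <- attr(pool, "attempts")
    E0 <- attr(pool, "E0")
  } else {
    pool <- initial_pool
    attempts <- nrow(pool)
    E0 <- config$E0 %||% min(pool$energy_eV)
    pool$scaled_energy <- scale_energy(pool$energy_eV, E0)
  }

  bank <- NULL
  latent_log <- list()
  curve <- list()
  invalid_total <- 0L
  vae <- NULL
  stopped_at <- NA_integer_

  for (t in seq_len(config$M)) {
    pool <- vae_cutoff(pool, config$alpha)
    train <- dplyr::filter(pool, .data$vae_included)
    Xn <- normalize_angles(pool_angles(train), ranges)
    vcfg <- vae_config(D, layersize = config$layersize,
                       latent_dim = config$latent_dim,
                       lambda = config$lambda, beta = config$beta,
                       epochs = config$epochs, patience = config$patience,
                       rtol = config$rtol, seed = derive_seed(seed, t))
    vae <- train_vae(Xn, train$scaled_energy, vcfg,
                     init = if (config$warm_start) vae else NULL)
    enc <- encode(vae, Xn, train$scaled_energy)
    z <- enc$mu
    latent_log[[t]] <- tibble(z1 = z[, 1],
                              z2 = if (ncol(z) >= 2) z[, 2] else NA_real_,
                              scaled_energy = train$scaled_energy,
                              iteration = t)
    rect <- make_rectangle(z, config$expansion_rate)
    zb <- draw_batch(rect, config$batch_size, seed = derive_seed(seed, 100000 + t))
    xb <- decode(vae, zb, clip = TRUE)
    ab <- denormalize_angles(xb, ranges)
    E <- evaluate_energy(backend, ab)
    attempts <- attempts + nrow(ab)
    bad <- is.na(E)
    if (mean(bad) > 0.5) {
      abort(paste0("backend failure rate ", round(100 * mean(bad)),
                   "% in iteration ", t, "; aborting"))
    }
    invalid_total <- invalid_total + sum(bad)
    if (any(!bad)) {
      pool <- dplyr::bind_rows(
        pool, make_pool(ab[!bad, , drop = FALSE], E[!bad], E0,
                        iteration = t, run_id = run_id))
    }

    if (t %% config$k == 0 || t == config$M) {
      bm <- bank_minima(pool, ranges, config$noise, t, run_id)
      bank <- dplyr::bind_rows(bank, bm$minima)
      if (!is.null(targets)) {
        rep_t <- match_targets(bank, targets, ranges = ranges)
        curve[[length(curve) + 1]] <- tibble(
          iteration = t, samples = nrow(pool),
          achieved = rep_t$n_achieved,
          global_min = rep_t$global_min_achieved)
        if (stop_check(rep_t, min_frac = config$stop_frac)) {
          stopped_at <- t
          break
        }
      }
    }
  }

  refined <- refine_candidates(bank, backend,
                               max_steps = config$refine_max_steps,
                               force_tol = config$refine_force_tol,
                               ranges = ranges)
  structure(list(
    conformers = refined$conformers,
    pool = pool, bank = bank,
    latent = dplyr::bind_rows(latent_log),
    curve = dplyr::bind_rows(curve),
    counts = list(single = attempts, relax = refined$relax,
                  converged = refined$converged),
    invalid = invalid_total, E0 = E0,
    stopped_at = stopped_at, config = config, run_id = run_id,
    vae = vae
  ), class = "lols_run")
}

#' @export
print.lols_run <- function(x, ...) {
  cat("<lols_run> run", x$run_id, ": pool", nrow(x$pool), "records,",
      nrow(x$conformers), "conformer(s)\n")
  cat("  single:", x$counts$single, " relax:", x$counts$relax,
      " converged:", x$counts$converged, " invalid:", x$invalid, "\n")
  if (!is.na(x$stopped_at)) cat("  early stop at iteration", x$stopped_at, "\n")
  invisible(x)
}

#' Refine candidate minima on the true backend energy
#'
#' Local minimization of each candidate on the backend (conjugate
#' gradients with the backend's analytic gradient where available),
#' declared converged when the gradient norm falls below `force_tol`
#' within `max_steps` iterations.  Non-converged candidates are excluded
#' and counted.  Survivors are deduplicated with [merge_similar()] and
#' re-referenced to the new global minimum.
#'
#' @param candidates Tibble with `angle_*` columns (e.g. a minima bank).
#' @param backend An `energy_backend`.
#' @param max_steps Maximum minimization steps; default 200.
#' @param force_tol Gradient-norm threshold in eV/degree; default 0.01.
#' @param ranges Optional ranges tibble.
#' @return List with `conformers` (tibble: angles, `energy_eV`,
#'   `rel_energy`, provenance, `converged`), `relax` (candidates
#'   refined), `converged` (count).
#' @export
refine_candidates <- function(candidates, backend, max_steps = 200,
                              force_tol = 0.01, ranges = NULL) {
  D <- backend$dim
  ranges <- as_ranges(ranges %||% backend$ranges, D)
  empty <- tibble::as_tibble(setNames(
    as.data.frame(matrix(numeric(0), 0, D)), angle_cols(D)))
  empty$energy_eV <- numeric(0); empty$rel_energy <- numeric(0)
  empty$model_index <- integer(0); empty$run_id <- integer(0)
  empty$converged <- logical(0)
  if (is.null(candidates) || nrow(candidates) == 0) {
    return(list(conformers = empty, relax = 0L, converged = 0L))
  }
  A <- pool_angles(candidates)
  fn <- function(x) evaluate_energy(backend, x)
  gr <- function(x) backend_gradient(backend, x)
  pscale <- (ranges$high - ranges$low) / 8
  rows <- vector("list", nrow(A))
  n_conv <- 0L
  for (i in seq_len(nrow(A))) {
    opt <- stats::optim(A[i, ], fn, gr, method = "CG",
                        control = list(reltol = 1e-12, maxit = max_steps,
                                       parscale = pscale))
    gn <- sqrt(sum(gr(opt$par)^2))
    conv <- gn <= force_tol
    if (conv) {
      # tight polish at the converged point
      opt <- stats::optim(opt$par, fn, gr, method = "BFGS",
                          control = list(reltol = 1e-14, maxit = 100,
                                         parscale = pscale))
      n_conv <- n_conv + 1L
      rows[[i]] <- c(wrap_angles(opt$par, ranges), opt$value, i)
    }
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(list(conformers = empty, relax = nrow(A), converged = 0L))
  }
  out <- tibble::as_tibble(as.data.frame(rows[, seq_len(D), drop = FALSE]))
  names(out) <- angle_cols(D)
  out$energy_eV <- rows[, D + 1]
  src <- as.integer(rows[, D + 2])
  out$model_index <- if ("model_index" %in% names(candidates))
    candidates$model_index[src] else NA_integer_
  out$run_id <- if ("run_id" %in% names(candidates))
    candidates$run_id[src] else NA_integer_
  out$converged <- TRUE
  out <- merge_similar(out, ranges = ranges, energy_col = "energy_eV")
  out$rel_energy <- out$energy_eV - min(out$energy_eV)
  list(conformers = out, relax = nrow(A), converged = n_conv)
}

#' Compare search results against reference targets
#'
#' A target is achieved when some result lies within a maximum circular
#' dihedral difference below `threshold` (15 degrees by convention) in
#' every dimension.  Results that match no target but lie below the highest
#' target energy are counted as new conformers.
#'
#' @param results Tibble with `angle_*` columns and an energy column
#'   (`rel_energy` used when present for the "new" energy window).
#' @param targets Tibble with `angle_*` and `rel_energy` (or `energy`).
#' @param ranges Optional ranges tibble.
#' @param threshold Max-difference threshold in degrees; default 15.
#' @return List: `targets` (with `achieved` flag), `results` (with
#'   `matched_target`, `is_new`), `n_achieved`, `frac_achieved`,
#'   `global_min_achieved`.
#' @export
match_targets <- function(results, targets, ranges = NULL, threshold = 15) {
  D <- length(grep("^angle_", names(results)))
  ranges <- as_ranges(ranges, D)
  R <- pool_angles(results)
  if (is.null(targets) || nrow(targets) == 0) {
    results$matched_target <- NA_integer_
    results$is_new <- TRUE
    return(list(targets = targets, results = results,
                n_achieved = 0L, frac_achieved = NA_real_,
                global_min_achieved = NA))
  }
  Tm <- pool_angles(targets)
  t_energy <- targets[["rel_energy"]] %||% targets[["energy"]]
  achieved <- logical(nrow(Tm))
  matched <- rep(NA_integer_, nrow(R))
  if (nrow(R)) {
    for (it in seq_len(nrow(Tm))) {
      dmax <- rep(0, nrow(R))
      for (j in seq_len(D)) {
        dj <- abs(R[, j] - Tm[it, j])
        if (ranges$periodic[j]) {
          span <- ranges$high[j] - ranges$low[j]
          dj <- dj %% span
          dj <- pmin(dj, span - dj)
        }
        dmax <- pmax(dmax, dj)
      }
      hit <- which(dmax < threshold)
      achieved[it] <- length(hit) > 0
      matched[hit[is.na(matched[hit])]] <- it
    }
  }
  targets$achieved <- achieved
  results$matched_target <- matched
  r_energy <- results[["rel_energy"]] %||% results[["energy"]]
  results$is_new <- is.na(matched) &
    (if (!is.null(r_energy)) r_energy <= max(t_energy) else TRUE)
  gm <- which.min(t_energy)
  list(targets = targets, results = results,
       n_achieved = sum(achieved),
       frac_achieved = mean(achieved),
       global_min_achieved = achieved[gm])
}

#' Early-stopping rule of the benchmark mode
#'
#' `TRUE` when the global-minimum target has been achieved and at least
#' `min_frac` (default 70%) of all reference targets are achieved.  Only
#' meaningful when reference targets are configured; without targets the
#' loop always runs to its maximum iteration.
#'
#' @param report A [match_targets()] report.
#' @param min_frac Required achieved fraction; default 0.7.
#' @return Logical.
#' @export
stop_check <- function(report, min_frac = 0.7) {
  if (is.null(report$targets) || isTRUE(is.na(report$global_min_achieved))) {
    return(FALSE)
  }
  isTRUE(report$global_min_achieved) &&
    isTRUE(report$frac_achieved >= min_frac)
}

#' Random real-space baseline search
#'
#' Identical downstream pipeline to [run_lols()] (periodic GP fit every
#' `k` iterations, minima banking, refinement, deduplication, matching)
#' but candidate batches are drawn uniformly in real space instead of from
#' the VAE latent space.
#'
#' @inheritParams run_lols
#' @return An `lols_run` object (with empty latent snapshots).
#' @export
run_real_space_baseline <- function(backend, config = lols_config(),
                                    targets = NULL, run_id = 1L) {
  ranges <- backend$ranges
  D <- backend$dim
  seed <- as.integer(config$seed)
  pool <- generate_initial_data(backend, config$initdata, seed = seed,
                                E0 = config$E0, run_id = run_id)
  attempts <- attr(pool, "attempts")
  E0 <- attr(pool, "E0")
  bank <- NULL
  curve <- list()
  invalid_total <- 0L
  stopped_at <- NA_integer_
  for (t in seq_len(config$M)) {
    ab <- withr::with_seed(derive_seed(seed, 200000 + t), {
      u <- matrix(stats::runif(config$batch_size * D), config$batch_size, D)
      sweep(sweep(u, 2, ranges$high - ranges$low, "*"), 2, ranges$low, "+")
    })
    E <- evaluate_energy(backend, ab)
    attempts <- attempts + nrow(ab)
    bad <- is.na(E)
    invalid_total <- invalid_total + sum(bad)
    if (any(!bad)) {
      pool <- dplyr::bind_rows(
        pool, make_pool(ab[!bad, , drop = FALSE], E[!bad], E0,
                        iteration = t, run_id = run_id))
    }
    if (t %% config$k == 0 || t == config$M) {
      bm <- bank_minima(pool, ranges, config$noise, t, run_id)
      bank <- dplyr::bind_rows(bank, bm$minima)
      if (!is.null(targets)) {
        rep_t <- match_targets(bank, targets, ranges = ranges)
        curve[[length(curve) + 1]] <- tibble(
          iteration = t, samples = nrow(pool),
          achieved = rep_t$n_achieved,
          global_min = rep_t$global_min_achieved)
        if (stop_check(rep_t, min_frac = config$stop_frac)) {
          stopped_at <- t
          break
        }
      }
    }
  }
  refined <- refine_candidates(bank, backend,
                               max_steps = config$refine_max_steps,
                               force_tol = config$refine_force_tol,
                               ranges = ranges)
  structure(list(
    conformers = refined$conformers, pool = pool, bank = bank,
    latent = tibble(), curve = dplyr::bind_rows(curve),
    counts = list(single = attempts, relax = refined$relax,
                  converged = refined$converged),
    invalid = invalid_total, E0 = E0, stopped_at = stopped_at,
    config = config, run_id = run_id, vae = NULL
  ), class = "lols_run")
}

#' Merge parallel runs
#'
#' Union of the refined conformers of several seeded runs, deduplicated
#' with [merge_similar()] and re-referenced to the merged global minimum.
#' Parallel runs average out the randomization of the sampling; the merged
#' achieved count is never below any individual run's.
#'
#' @param runs List of `lols_run` objects.
#' @param ranges Optional ranges tibble.
#' @return List: `conformers` (merged tibble) and `counts` (summed
#'   bookkeeping).
#' @export
merge_runs <- function(runs, ranges = NULL) {
  all <- dplyr::bind_rows(lapply(runs, function(r) r$conformers))
  D <- length(grep("^angle_", names(all)))
  ranges <- as_ranges(ranges, D)
  merged <- merge_similar(all, ranges = ranges, energy_col = "energy_eV")
  if (nrow(merged)) merged$rel_energy <- merged$energy_eV - min(merged$energy_eV)
  counts <- list(
    single = sum(vapply(runs, function(r) r$counts$single, numeric(1))),
    relax = sum(vapply(runs, function(r) r$counts$relax, numeric(1))),
    converged = sum(vapply(runs, function(r) r$counts$converged, numeric(1)))
  )
  list(conformers = merged, counts = counts)
}

#' Map target islands in the latent space
#'
#' Discretizes the bounding rectangle of the latent points on a
#' `grid_n`-by-`grid_n` grid, decodes every grid point to dihedral space,
#' and assigns it to the nearest reference conformer when the mean circular
#' dihedral difference is below `threshold` (30 degrees).  Reports the area
#' fraction of each target's island(s) and the total fraction for targets
#' inside the energy window.
#'
#' @param model A trained `lols_vae`.
#' @param z N-by-d matrix of latent points (encoded training data).
#' @param targets Reference conformers (`angle_*`, `rel_energy`).
#' @param ranges Optional ranges tibble.
#' @param grid_n Grid resolution per axis (400 in production analyses).
#' @param threshold Mean-difference assignment threshold; default 30.
#' @param energy_window Only targets with `rel_energy` at or below this
#'   window (eV) enter the map; default 0.5.
#' @return An `lols_islands` object: per-target tibble `areas` and the
#'   scalar `total_area_fraction`.
#' @export
map_latent_islands <- function(model, z, targets, ranges = NULL,
                               grid_n = 400, threshold = 30,
                               energy_window = 0.5) {
  D <- model$config$input_dim
  ranges <- as_ranges(ranges, D)
  keep <- which((targets[["rel_energy"]] %||% targets[["energy"]]) <= energy_window)
  targets <- targets[keep, , drop = FALSE]
  rect <- make_rectangle(z, rate = 0)
  g1 <- seq(rect$lower[1], rect$upper[1], length.out = grid_n)
  g2 <- seq(rect$lower[2], rect$upper[2], length.out = grid_n)
  grid <- as.matrix(expand.grid(z1 = g1, z2 = g2))
  dec <- decode(model, grid, clip = TRUE)
  ang <- denormalize_angles(dec, ranges)
  n <- nrow(ang)
  if (nrow(targets) == 0) {
    return(structure(list(
      areas = tibble(target = integer(0), area_fraction = numeric(0)),
      total_area_fraction = 0, grid_n = grid_n,
      assignment = tibble(z1 = grid[, 1], z2 = grid[, 2],
                          target = NA_integer_)),
      class = "lols_islands"))
  }
  Tm <- pool_angles(targets)
  span <- ranges$high - ranges$low
  best_d <- rep(Inf, n)
  best_t <- rep(NA_integer_, n)
  for (it in seq_len(nrow(Tm))) {
    dm <- rep(0, n)
    for (j in seq_len(D)) {
      dj <- abs(ang[, j] - Tm[it, j])
      if (ranges$periodic[j]) {
        dj <- dj %% span[j]
        dj <- pmin(dj, span[j] - dj)
      }
      dm <- dm + dj
    }
    dm <- dm / D
    upd <- dm < best_d
    best_d[upd] <- dm[upd]
    best_t[upd] <- it
  }
  best_t[best_d >= threshold] <- NA_integer_
  areas <- tibble(target = seq_len(nrow(Tm)),
                  area_fraction = vapply(seq_len(nrow(Tm)), function(it) {
                    mean(!is.na(best_t) & best_t == it)
                  }, numeric(1)))
  structure(list(areas = areas,
                 total_area_fraction = mean(!is.na(best_t)),
                 grid_n = grid_n,
                 assignment = tibble(z1 = grid[, 1], z2 = grid[, 2],
                                     target = best_t)),
            class = "lols_islands")
}

#' @export
print.lols_islands <- function(x, ...) {
  cat("<lols_islands>", nrow(x$areas), "target(s), total area",
      sprintf("%.2f%%", 100 * x$total_area_fraction),
      "of the latent rectangle\n")
  invisible(x)
}

#' @method tidy lols_run
#' @export
tidy.lols_run <- function(x, ...) x$conformers

#' @method glance lols_run
#' @export
glance.lols_run <- function(x, ...) {
  tibble(n_conformers = nrow(x$conformers),
         pool_size = nrow(x$pool),
         single = x$counts$single,
         relax = x$counts$relax,
         converged = x$counts$converged,
         invalid = x$invalid,
         stopped_at = x$stopped_at,
         E0 = x$E0)
}

#' Export a run's conformers and pool to files
#'
#' Writes the minima table (TSV), the data pool (TSV) and, when a molecule
#' spec is supplied, a multi-frame XYZ of the conformers, plus a JSON run
#' report.
#'
#' @param run An `lols_run`.
#' @param dir Output directory.
#' @param spec Optional [molecule_spec()] for structure realization.
#' @export
write_run <- function(run, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$conformers, file.path(dir, "conformers.tsv"))
  write_pool(run$pool, file.path(dir, "pool.tsv"))
  if (nrow(run$latent)) {
    readr::write_tsv(run$latent, file.path(dir, "latent.tsv"))
  }
  report <- list(counts = run$counts, invalid = run$invalid,
                 E0 = run$E0, stopped_at = run$stopped_at,
                 curve = run$curve)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  if (!is.null(spec) && nrow(run$conformers)) {
    frames <- lapply(seq_len(nrow(run$conformers)), function(i) {
      apply_dihedrals(spec, as.numeric(
        run$conformers[i, angle_cols(spec$D)]))
    })
    write_xyz(frames, file.path(dir, "conformers.xyz"), spec = spec,
              comments = sprintf("E = %.8f eV", run$conformers$energy_eV))
  }
  invisible(dir)
}
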