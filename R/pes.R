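#' Construct a synthetic periodic multi-well torsional energy surface
#'
#' The test stand-in for a quantum-chemistry backend: a smooth, fully
#' periodic energy function over `dim` torsions whose local minima can be
#' enumerated exactly by brute force.  Each dimension carries a torsional
#' profile of the familiar cosine-series form,
#' `A/2 * (1 - cos(k * (theta - phase))) + b/2 * (1 - cos(theta - psi))`:
#' the dominant `k`-fold term places `k` wells per dimension and the small
#' single-period tilt (`b < A`) breaks their degeneracy, so the profile has
#' well-defined curvature everywhere and no flat shelves.  Weak pairwise
#' couplings `c * (1 - cos(theta_j - theta_k - phase)) / 2` tilt the
#' landscape without changing the well count.  The per-dimension well
#' multiplicities factorize `n_wells`, so the total minima count is close
#' to `n_wells`.  The construction deterministically strengthens the tilt
#' until the global minimum is separated from the runner-up by at least
#' 5 meV.
#'
#' @param dim Number of torsions `D`.
#' @param n_wells Approximate number of local minima on the full surface.
#' @param coupling_strength Scale of the pairwise couplings in eV; default
#'   0.03 (weak relative to well depths of 0.1-0.3 eV).
#' @param seed Integer seed; the construction is deterministic per seed.
#' @param base_energy Additive offset in eV.  The default of about -2e4 eV
#'   mimics the raw total energies of quantum-chemistry engines and
#'   exercises the threshold-shift (`E0`) pathway realistically.
#' @return A `synthetic_pes` object.
#' @export
make_synthetic_pes <- function(dim, n_wells, coupling_strength = 0.03,
                               seed = 1L, base_energy = -20000) {
  stopifnot(dim >= 1, n_wells >= 1)
  withr::with_seed(as.integer(seed), {
    kj <- factorize_wells(n_wells, dim)
    wells <- lapply(seq_len(dim), function(j) {
      tibble(k = kj[j],
             A = stats::runif(1, 0.15, 0.30),
             phase = stats::runif(1, 0, 360),
             b = stats::runif(1, 0.02, 0.05),
             psi = stats::runif(1, 0, 360))
    })
    pairs <- if (dim >= 2 && coupling_strength > 0) {
      tibble(j = seq_len(dim - 1), k = seq_len(dim - 1) + 1L,
             c = coupling_strength * stats::runif(dim - 1, 0.5, 1),
             phase = stats::runif(dim - 1, 0, 360))
    } else {
      tibble(j = integer(0), k = integer(0), c = numeric(0), phase = numeric(0))
    }
    pes <- structure(list(dim = dim, wells = wells, pairs = pairs,
                          base_energy = base_energy, seed = as.integer(seed),
                          span = 360),
                     class = "synthetic_pes")
    ensure_min_gap(pes, gap = 0.005)
  })
}

# Per-dimension well counts whose product best approximates n_wells.
# Multiplicities are capped at 3 (two- and three-fold rotamer-like
# profiles): higher multiplicities space wells so closely that distinct
# minima fall below the 15-degree mean-distance similarity rule in
# moderate dimensions.
factorize_wells <- function(n_wells, dim) {
  best <- NULL
  best_err <- Inf
  for (a in 0:dim) {          # number of three-fold dims
    for (b in 0:(dim - a)) {  # number of two-fold dims
      p <- 3^a * 2^b
      err <- abs(p - n_wells)
      if (err < best_err || (err == best_err && p > prod(best %||% 0))) {
        best <- c(rep(3L, a), rep(2L, b), rep(1L, dim - a - b))
        best_err <- err
      }
    }
  }
  best
}

# Deepen the global-minimum well until the gap to the runner-up is >= `gap`.
ensure_min_gap <- function(pes, gap = 0.005, max_tries = 25) {
  for (try in seq_len(max_tries)) {
    m <- polish_center_products(pes)
    if (nrow(m) < 2 || m$energy[2] - m$energy[1] >= gap) return(pes)
    gm <- as.numeric(m[1, angle_cols(pes$dim)])
    # point each dimension's tilt minimum at the global minimum and
    # strengthen it slightly; repeats until the gap opens
    for (j in seq_len(pes$dim)) {
      pes$wells[[j]]$psi <- gm[j]
      pes$wells[[j]]$b <- min(pes$wells[[j]]$b + 0.005,
                              0.3 * pes$wells[[j]]$A)
    }
  }
  warn("could not separate global minimum by 5 meV; using final surface")
  pes
}

circ_diff360 <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Minima located by polishing every product of per-dimension well centers.
polish_center_products <- function(pes) {
  grids <- lapply(pes$wells, function(w) {
    (w$phase + (seq_len(w$k) - 1) * 360 / w$k) %% 360
  })
  starts <- as.matrix(expand.grid(grids))
  polished <- t(apply(starts, 1, function(s) polish_minimum(pes, s)))
  cands <- tibble::as_tibble(as.data.frame(polished[, seq_len(pes$dim), drop = FALSE]))
  names(cands) <- angle_cols(pes$dim)
  cands$energy <- polished[, pes$dim + 1]
  merge_similar(cands, ranges = full_ranges(pes$dim), energy_col = "energy")
}

polish_minimum <- function(pes, start, gtol = 1e-6) {
  fn <- function(x) pes_energy(pes, x)
  gr <- function(x) pes_gradient(pes, x)
  ctl <- list(reltol = 1e-14, maxit = 500, parscale = rep(45, pes$dim))
  res <- stats::optim(start, fn, gr, method = "BFGS", control = ctl)
  for (r in 1:3) {
    if (sqrt(sum(pes_gradient(pes, res$par)^2)) <= gtol) break
    res <- stats::optim(res$par, fn, gr, method = "BFGS", control = ctl)
  }
  c(res$par %% 360, res$value)
}

#' @export
print.synthetic_pes <- function(x, ...) {
  cat("<synthetic_pes> dim =", x$dim, " wells/dim:",
      paste(vapply(x$wells, function(w) w$k, numeric(1)), collapse = "x"),
      " couplings:", nrow(x$pairs), " base:", x$base_energy, "eV\n")
  invisible(x)
}

#' Evaluate the synthetic surface
#'
#' @param pes A `synthetic_pes`.
#' @param angles Degree vector of length `dim`, or an N-by-dim matrix.
#' @return Energy in eV (vector of length N).
#' @export
pes_energy <- function(pes, angles) {
  X <- rbind(angles)
  E <- rep(pes$base_energy, nrow(X))
  for (j in seq_len(pes$dim)) {
    w <- pes$wells[[j]]
    E <- E + w$A / 2 * (1 - cos(w$k * (X[, j] - w$phase) * DEG2RAD)) +
      w$b / 2 * (1 - cos((X[, j] - w$psi) * DEG2RAD))
  }
  p <- pes$pairs
  for (i in seq_len(nrow(p))) {
    E <- E + p$c[i] * (1 - cos((X[, p$j[i]] - X[, p$k[i]] - p$phase[i]) * DEG2RAD)) / 2
  }
  unname(E)
}

#' Analytic gradient of the synthetic surface
#'
#' @param pes A `synthetic_pes`.
#' @param angles Degree vector of length `dim`.
#' @return Gradient vector in eV/degree.
#' @export
pes_gradient <- function(pes, angles) {
  g <- numeric(pes$dim)
  for (j in seq_len(pes$dim)) {
    w <- pes$wells[[j]]
    g[j] <- (w$A / 2 * w$k * sin(w$k * (angles[j] - w$phase) * DEG2RAD) +
               w$b / 2 * sin((angles[j] - w$psi) * DEG2RAD)) * DEG2RAD
  }
  p <- pes$pairs
  for (i in seq_len(nrow(p))) {
    d <- (angles[p$j[i]] - angles[p$k[i]] - p$phase[i]) * DEG2RAD
    term <- p$c[i] / 2 * sin(d) * DEG2RAD
    g[p$j[i]] <- g[p$j[i]] + term
    g[p$k[i]] <- g[p$k[i]] - term
  }
  g
}

#' Energy backends
#'
#' A backend is the energy oracle of the workflow: it maps a dihedral vector
#' to a raw energy in eV or flags the structure invalid.  Three kinds are
#' provided: the synthetic surface ([make_synthetic_pes()]), an arbitrary R
#' callable, and a templated external program (quantum-chemistry engine
#' stub).
#'
#' @param pes A `synthetic_pes`.
#' @return An `energy_backend` object.
#' @export
synthetic_backend <- function(pes) {
  structure(list(type = "synthetic", pes = pes, dim = pes$dim,
                 ranges = full_ranges(pes$dim)),
            class = "energy_backend")
}

#' @rdname synthetic_backend
#' @param fn Function mapping a degree vector to an energy in eV (or `NA`
#'   for an invalid structure).
#' @param dim Search dimensionality.
#' @param grad Optional analytic gradient function (eV/degree); finite
#'   differences are used when absent.
#' @param ranges Optional ranges tibble.
#' @export
callable_backend <- function(fn, dim, grad = NULL, ranges = NULL) {
  structure(list(type = "callable", fn = fn, grad = grad, dim = dim,
                 ranges = as_ranges(ranges, dim)),
            class = "energy_backend")
}

#' @rdname synthetic_backend
#' @param command Command template containing `{xyz}`, replaced by the path
#'   of the structure file written for each evaluation.  The external
#'   program must print a single final energy in eV as the last numeric
#'   token of its standard output; a non-zero exit status or unparseable
#'   output marks the structure invalid.
#' @param spec A [molecule_spec()] used to realize structures and detect
#'   clashes before the program is invoked.
#' @param clash_scale Covalent-radius fraction for [detect_clash()].
#' @param workdir Scratch directory for structure files.
#' @export
external_backend <- function(command, spec, clash_scale = 0.7,
                             workdir = tempdir()) {
  structure(list(type = "external", command = command, spec = spec,
                 clash_scale = clash_scale, workdir = workdir,
                 dim = spec$D, ranges = spec$ranges),
            class = "energy_backend")
}

#' @rdname synthetic_backend
#' @param mspec Optional [molecule_spec()]: when supplied together with a
#'   synthetic or callable backend, structures are realized and
#'   clash-checked before evaluation.
#' @param backend An `energy_backend`.
#' @export
with_molecule <- function(backend, mspec, clash_scale = 0.7) {
  backend$spec <- mspec
  backend$clash_scale <- clash_scale
  backend$ranges <- mspec$ranges
  backend
}

#' Evaluate a backend on one conformation or a batch
#'
#' @param backend An `energy_backend`.
#' @param conf A `conformation`, a degree vector, or an N-by-D matrix.
#' @return Numeric energies in eV; `NA` marks invalid structures (steric
#'   clash or failed external evaluation).
#' @export
evaluate_energy <- function(backend, conf) {
  X <- if (inherits(conf, "conformation")) rbind(conf$angles) else rbind(conf)
  n <- nrow(X)
  # clash screening when a molecule spec is attached
  valid <- rep(TRUE, n)
  if (!is.null(backend$spec)) {
    for (i in seq_len(n)) {
      cf <- apply_dihedrals(backend$spec, X[i, ])
      if (detect_clash(cf, backend$spec, backend$clash_scale %||% 0.7)) {
        valid[i] <- FALSE
      }
    }
  }
  E <- rep(NA_real_, n)
  if (backend$type == "synthetic") {
    E[valid] <- pes_energy(backend$pes, X[valid, , drop = FALSE])
  } else if (backend$type == "callable") {
    E[valid] <- vapply(which(valid), function(i) backend$fn(X[i, ]), numeric(1))
  } else if (backend$type == "external") {
    for (i in which(valid)) {
      E[i] <- run_external_energy(backend, X[i, ])
    }
  } else {
    abort("unknown backend type")
  }
  E
}

backend_gradient <- function(backend, x, h = 1e-4) {
  if (backend$type == "synthetic") return(pes_gradient(backend$pes, x))
  if (!is.null(backend$grad)) return(backend$grad(x))
  # central finite differences as fallback
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    (evaluate_energy(backend, xp) - evaluate_energy(backend, xm)) / (2 * h)
  }, numeric(1))
}

run_external_energy <- function(backend, angles) {
  cf <- apply_dihedrals(backend$spec, angles)
  xyz <- file.path(backend$workdir, "lols_eval.xyz")
  write_xyz(cf, xyz, spec = backend$spec)
  cmd <- gsub("{xyz}", xyz, backend$command, fixed = TRUE)
  out <- tryCatch(
    suppressWarnings(system(cmd, intern = TRUE)),
    error = function(e) NULL
  )
  if (is.null(out) || !is.null(attr(out, "status"))) return(NA_real_)
  nums <- suppressWarnings(as.numeric(unlist(
    regmatches(out, gregexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", out)))))
  nums <- nums[is.finite(nums)]
  if (!length(nums)) NA_real_ else nums[length(nums)]
}

#' Enumerate all local minima of a synthetic surface by brute force
#'
#' Scans the full periodic grid (`grid_points_per_dim` points per torsion),
#' keeps grid points strictly below all axis neighbors (periodic wrap),
#' polishes each by local minimization with the analytic gradient,
#' deduplicates under mean circular dihedral distance < 15 degrees keeping
#' the lowest-energy member, and sorts by energy.  This is the independent
#' oracle the workflow is benchmarked against.
#'
#' @param pes A `synthetic_pes`.
#' @param grid_points_per_dim Grid resolution; default 24 (15-degree steps).
#' @return Tibble with `angle_1..angle_D`, `energy` (eV), `rel_energy` (eV
#'   above the global minimum), sorted ascending.
#' @export
bruteforce_minima <- function(pes, grid_points_per_dim = 24) {
  n <- as.integer(grid_points_per_dim)
  D <- pes$dim
  kmax <- max(vapply(pes$wells, function(w) w$k, numeric(1)))
  if (n < 4 * kmax) {
    warn("grid may be too coarse to separate the declared wells")
  }
  g <- seq(0, 360, length.out = n + 1)[seq_len(n)]
  E <- array(pes$base_energy, rep(n, D))
  for (j in seq_len(D)) {
    w <- pes$wells[[j]]
    prof <- w$A / 2 * (1 - cos(w$k * (g - w$phase) * DEG2RAD)) +
      w$b / 2 * (1 - cos((g - w$psi) * DEG2RAD))
    E <- sweep(E, j, prof, "+")
  }
  p <- pes$pairs
  for (i in seq_len(nrow(p))) {
    P <- outer(g, g, function(a, b) {
      p$c[i] * (1 - cos((a - b - p$phase[i]) * DEG2RAD)) / 2
    })
    E <- sweep(E, c(p$j[i], p$k[i]), P, "+")
  }
  is_min <- array(TRUE, rep(n, D))
  for (j in seq_len(D)) {
    is_min <- is_min & (E < shift_margin(E, j, 1L)) & (E < shift_margin(E, j, -1L))
  }
  idx <- which(is_min, arr.ind = TRUE)
  idx <- matrix(idx, ncol = D)
  starts <- matrix(g[idx], ncol = D)
  polished <- t(apply(starts, 1, function(s) polish_minimum(pes, s)))
  out <- tibble::as_tibble(as.data.frame(polished[, seq_len(D), drop = FALSE]))
  names(out) <- angle_cols(D)
  out$energy <- polished[, D + 1]
  out <- merge_similar(out, ranges = full_ranges(D), energy_col = "energy")
  out$rel_energy <- out$energy - out$energy[1]
  out
}

# Circularly shift an array along one margin by s steps.
shift_margin <- function(A, margin, s) {
  dims <- dim(A)
  D <- length(dims)
  perm <- c(margin, seq_len(D)[-margin])
  B <- aperm(A, perm)
  n <- dims[margin]
  ord <- ((seq_len(n) - 1 + s) %% n) + 1
  Bm <- matrix(B, nrow = n)
  Bm <- Bm[ord, , drop = FALSE]
  B <- array(Bm, dim(B))
  aperm(B, order(perm))
}

#' Serialize a synthetic surface to a config file
#'
#' @param pes A `synthetic_pes`.
#' @param path YAML file path.
#' @export
write_pes <- function(pes, path) {
  yaml::write_yaml(precision = 15, list(
    dim = pes$dim, base_energy = pes$base_energy, seed = pes$seed,
    span = pes$span,
    wells = lapply(pes$wells, function(w) as.list(as.data.frame(w))),
    pairs = as.list(as.data.frame(pes$pairs))
  ), path)
  invisible(path)
}

#' @rdname write_pes
#' @export
read_pes <- function(path) {
  y <- yaml::read_yaml(path)
  structure(list(
    dim = y$dim,
    wells = lapply(y$wells, function(w) tibble(k = w$k, A = w$A,
                                               phase = w$phase,
                                               b = w$b, psi = w$psi)),
    pairs = tibble(j = as.integer(y$pairs$j %||% integer(0)),
                   k = as.integer(y$pairs$k %||% integer(0)),
                   c = as.numeric(y$pairs$c %||% numeric(0)),
                   phase = as.numeric(y$pairs$phase %||% numeric(0))),
    base_energy = y$base_energy, seed = y$seed, span = y$span %||% 360
  ), class = "synthetic_pes")
}
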