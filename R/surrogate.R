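# Gaussian-process energy model with a standard periodic kernel.
#
# k(x, x') = sf2 * prod_j exp(-2 sin^2(pi * d_j / p_j) / ell_j^2)
# with p_j the period (range span) of torsion j.  Observation noise is held
# fixed during fitting; lengthscales carry inverse-gamma priors.

periodic_kernel <- function(X1, X2, periods, sf2, ell) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  logK <- matrix(0, n1, n2)
  for (j in seq_len(ncol(X1))) {
    Dj <- outer(X1[, j], X2[, j], "-")
    logK <- logK - 2 * sin(pi * Dj / periods[j])^2 / ell[j]^2
  }
  sf2 * exp(logK)
}

# log density of inverse-gamma(shape a, scale b) at x
dinvgamma_log <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

#' Fit the real-space energy model
#'
#' Gaussian-process regression of the (scaled) energies on the dihedral
#' angles with a per-dimension standard periodic (exp-sine-squared) kernel
#' whose periods equal the range spans.  Kernel hyperparameters (signal
#' variance and per-dimension lengthscales) are chosen by maximizing the
#' marginal likelihood plus inverse-gamma log-priors on the lengthscales
#' (shape 2, scale 1: concentrating angular lengthscales in roughly the
#' 5-120 degree band).  The observation noise is held fixed (default
#' 0.001 eV, comparable to the accuracy of the reference energies); the GP
#' mean is the empirical mean of the targets.  The whole pool feeds the
#' model, including records excluded from VAE training by the alpha cutoff.
#'
#' @param pool Pool tibble (see [make_pool()]); needs at least `2 * D` rows.
#' @param ranges Optional ranges tibble; defaults to full 360-degree spans.
#' @param noise Fixed observation noise (standard deviation, eV).
#' @param target `"scaled"` (default) fits `E*`; `"raw"` fits `E`.  Because
#'   the energy scaling is monotone, minima locations are essentially
#'   unaffected by the choice.
#' @param n_starts Random restarts of the hyperparameter optimization.
#' @return An `lols_gp` model.
#' @export
fit_energy_model <- function(pool, ranges = NULL, noise = 0.001,
                             target = c("scaled", "raw"), n_starts = 2) {
  target <- match.arg(target)
  X <- pool_angles(pool)
  D <- ncol(X)
  ranges <- as_ranges(ranges, D)
  if (nrow(X) < 2 * D) abort("need at least 2*D records to fit the energy model")
  y <- if (target == "scaled") pool$scaled_energy else pool$energy_eV
  periods <- ranges$high - ranges$low
  m0 <- mean(y)
  yc <- y - m0
  n <- length(yc)

  neg_obj <- function(theta) {
    sf2 <- exp(theta[1]); ell <- exp(theta[-1])
    K <- periodic_kernel(X, X, periods, sf2, ell)
    diag(K) <- diag(K) + noise^2 + 1e-10
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    a <- backsolve(L, forwardsolve(t(L), yc))
    nll <- 0.5 * sum(yc * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
    nll - sum(dinvgamma_log(ell, 2, 1))
  }

  starts <- list(c(log(stats::var(yc) + 1e-12), rep(log(0.5), D)),
                 c(log(stats::var(yc) + 1e-12), rep(log(1.5), D)))
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  fits <- lapply(starts, function(s) {
    stats::optim(s, neg_obj, method = "L-BFGS-B",
                 lower = c(-20, rep(log(0.02), D)),
                 upper = c(20, rep(log(10), D)),
                 control = list(maxit = 200))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  sf2 <- exp(best$par[1]); ell <- exp(best$par[-1])

  K <- periodic_kernel(X, X, periods, sf2, ell)
  jitter <- 1e-10
  repeat {
    L <- tryCatch(chol(K + diag(noise^2 + jitter, n)), error = function(e) NULL)
    if (!is.null(L)) break
    jitter <- jitter * 100
    if (jitter > 1e-2) abort("kernel matrix not positive definite")
    warn("degenerate training data; increasing jitter")
  }
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(list(X = X, y = y, mean = m0, alpha = alpha, L = L,
                 sf2 = sf2, ell = ell, periods = periods, noise = noise,
                 ranges = ranges, target = target,
                 neg_log_marginal = best$value),
            class = "lols_gp")
}

#' @export
print.lols_gp <- function(x, ...) {
  cat("<lols_gp> n =", nrow(x$X), " D =", ncol(x$X),
      " sf =", signif(sqrt(x$sf2), 4),
      " ell =", paste(signif(x$ell, 3), collapse = ", "),
      " noise =", x$noise, "\n")
  invisible(x)
}

#' Posterior prediction of the energy model
#'
#' @param model An `lols_gp`.
#' @param angles Degree vector or N-by-D matrix.
#' @return Tibble with columns `mean` and `sd` (posterior standard
#'   deviation of the latent function).  Predictions are periodic in every
#'   dimension.
#' @export
predict_energy <- function(model, angles) {
  Xs <- rbind(angles)
  Ks <- periodic_kernel(Xs, model$X, model$periods, model$sf2, model$ell)
  mu <- model$mean + as.numeric(Ks %*% model$alpha)
  V <- forwardsolve(t(model$L), t(Ks))
  var <- pmax(model$sf2 - colSums(V^2), 0)
  tibble(mean = mu, sd = sqrt(var))
}

# Posterior mean only (no covariance solve): the hot path of minimization.
posterior_mean <- function(model, x) {
  Ks <- periodic_kernel(rbind(x), model$X, model$periods, model$sf2, model$ell)
  model$mean + sum(Ks[1, ] * model$alpha)
}

# Analytic gradient of the posterior mean, eV(scaled)/degree.
posterior_mean_grad <- function(model, x) {
  Xs <- rbind(x)
  Ks <- periodic_kernel(Xs, model$X, model$periods, model$sf2, model$ell)
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    Dj <- x[j] - model$X[, j]
    dlog <- -(2 * pi / (model$ell[j]^2 * model$periods[j])) *
      sin(2 * pi * Dj / model$periods[j])
    g[j] <- sum(model$alpha * Ks[1, ] * dlog)
  }
  g
}

#' Extract local minima of the posterior mean
#'
#' Conjugate-gradient minimization of the GP posterior mean started from
#' every training input (or a supplied start set), using the analytic
#' gradient and periodic coordinate wrapping.  Starts whose endpoint fails
#' the gradient-norm test are skipped.  When the pool exceeds `max_starts`
#' records, starts are subsampled uniformly (seeded) to bound cost.
#'
#' @param model An `lols_gp`.
#' @param starts Optional matrix of start points; defaults to the training
#'   inputs.
#' @param gtol Gradient-norm convergence threshold (eV/degree); default 1e-5.
#' @param max_starts Start-point thinning bound; default 5000.
#' @param seed Seed for thinning.
#' @return Tibble `angle_1..angle_D`, `energy` (posterior mean), one row per
#'   converged endpoint (not yet deduplicated; see [merge_similar()]).
#' @export
extract_local_minima <- function(model, starts = NULL, gtol = 1e-5,
                                 max_starts = 5000, seed = 1L) {
  if (is.null(starts)) starts <- model$X
  starts <- rbind(starts)
  if (nrow(starts) > max_starts) {
    keep <- withr::with_seed(seed, sample.int(nrow(starts), max_starts))
    starts <- starts[keep, , drop = FALSE]
  }
  fn <- function(x) posterior_mean(model, x)
  gr <- function(x) posterior_mean_grad(model, x)
  pscale <- model$periods / 8
  res <- vector("list", nrow(starts))
  skipped <- 0L
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[i, ], fn, gr, method = "CG",
                        control = list(reltol = 1e-10, maxit = 200,
                                       parscale = pscale))
    if (sqrt(sum(gr(opt$par)^2)) > gtol) {
      opt <- stats::optim(opt$par, fn, gr, method = "BFGS",
                          control = list(reltol = 1e-14, maxit = 300,
                                         parscale = pscale))
    }
    if (sqrt(sum(gr(opt$par)^2)) > gtol) { skipped <- skipped + 1L; next }
    res[[i]] <- c(wrap_angles(opt$par, model$ranges), opt$value)
  }
  if (skipped > 0) inform(paste0(skipped, " start(s) did not converge and were skipped"))
  res <- do.call(rbind, res)
  if (is.null(res)) {
    out <- as_tibble(matrix(numeric(0), 0, ncol(model$X) + 1), .name_repair = "minimal")
    names(out) <- c(angle_cols(ncol(model$X)), "energy")
    return(out)
  }
  out <- as_tibble(as.data.frame(res[, seq_len(ncol(model$X)), drop = FALSE]))
  names(out) <- angle_cols(ncol(model$X))
  out$energy <- res[, ncol(model$X) + 1]
  out
}

#' Purge duplicate minima
#'
#' Single-linkage grouping of candidates under mean circular dihedral
#' distance below `threshold` (15 degrees by convention); each group keeps
#' only its lowest-energy member (ties broken by lexicographic angle order
#' for determinism).  The result is sorted by energy and the operation is
#' idempotent.
#'
#' @param candidates Tibble with `angle_1..angle_D` and an energy column.
#' @param ranges Optional ranges tibble.
#' @param threshold Mean-distance threshold in degrees; default 15.
#' @param energy_col Name of the energy column; default `"energy"`.
#' @return Deduplicated tibble sorted by energy.
#' @export
merge_similar <- function(candidates, ranges = NULL, threshold = 15,
                          energy_col = "energy") {
  n <- nrow(candidates)
  if (n <= 1) return(candidates)
  A <- pool_angles(candidates)
  ranges <- as_ranges(ranges, ncol(A))
  dm <- matrix(0, n, n)
  span <- ranges$high - ranges$low
  for (j in seq_len(ncol(A))) {
    dj <- abs(outer(A[, j], A[, j], "-"))
    if (ranges$periodic[j]) {
      dj <- dj %% span[j]
      dj <- pmin(dj, span[j] - dj)
    }
    dm <- dm + dj
  }
  dm <- dm / ncol(A)
  # connected components of the "similar" graph = single-linkage groups
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(dm[i, ] < threshold)
      newc <- min(comp[nb])
      if (any(comp[nb] != newc)) { comp[nb] <- newc; changed <- TRUE }
    }
    if (!changed) break
  }
  E <- candidates[[energy_col]]
  keep <- vapply(unique(comp), function(cc) {
    members <- which(comp == cc)
    best <- members[E[members] == min(E[members])]
    if (length(best) > 1) {
      ord <- do.call(order, as.data.frame(A[best, , drop = FALSE]))
      best <- best[ord[1]]
    }
    best
  }, integer(1))
  out <- candidates[keep, , drop = FALSE]
  out[order(out[[energy_col]]), , drop = FALSE]
}

#' @method tidy lols_gp
#' @export
tidy.lols_gp <- function(x, ...) {
  tibble(term = c("signal_sd", paste0("lengthscale_", seq_along(x$ell)),
                  "noise_sd"),
         estimate = c(sqrt(x$sf2), x$ell, x$noise))
}

#' @method glance lols_gp
#' @export
glance.lols_gp <- function(x, ...) {
  tibble(n = nrow(x$X), D = ncol(x$X),
         neg_log_marginal = x$neg_log_marginal,
         noise = x$noise, target = x$target)
}
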