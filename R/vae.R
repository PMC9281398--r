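#' Configuration of the energy-weighted variational auto-encoder
#'
#' The encoder takes the normalized dihedral vector concatenated with the
#' scaled energy `E*` and maps it through two fully connected ReLU layers of
#' `layersize` neurons each onto the mean and log-variance of a diagonal
#' Gaussian in a `latent_dim`-dimensional latent space.  The decoder mirrors
#' the architecture and outputs dihedrals only (no energy).  The
#' reconstruction loss of each sample is weighted by `exp(beta * E*)`: a
#' negative `beta` down-weights high-energy structures so the latent space
#' preferentially encodes the low-energy part of the surface.
#'
#' @param input_dim Number of free dihedrals `D`.
#' @param layersize Neurons per hidden layer; 80 is the production default
#'   for 5-dimensional searches, 128 for 7-9 dimensions.
#' @param latent_dim Latent dimensionality `d`; default 2.
#' @param lambda Loss ratio between reconstruction and KL terms; default 0.01.
#' @param beta Energy weight (<= 0); default 0 (unweighted).
#' @param epochs Maximum training epochs; default 1e5 with plateau-based
#'   early stopping.
#' @param learning_rate Adam step size; default 1e-3.
#' @param patience Plateau window (epochs) for early stopping; default 1000.
#' @param rtol Relative loss-improvement threshold declaring a plateau;
#'   default 1e-5.
#' @param seed Integer seed controlling initialization and reparameterization
#'   noise.
#' @return A `vae_config` list.
#' @export
vae_config <- function(input_dim, layersize = 80, latent_dim = 2,
                       lambda = 0.01, beta = 0, epochs = 1e5,
                       learning_rate = 1e-3, patience = 1000, rtol = 1e-5,
                       seed = 1L) {
  stopifnot(layersize >= 1, latent_dim >= 1, lambda > 0 || lambda == 0,
            beta <= 0, input_dim >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 layersize = as.integer(layersize),
                 latent_dim = as.integer(latent_dim),
                 lambda = lambda, beta = beta,
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 patience = as.integer(patience), rtol = rtol,
                 seed = as.integer(seed)),
            class = "vae_config")
}

relu <- function(x) (x > 0) * x

# He-initialized parameter set; b_lv starts at 0 so sigma^2 starts at 1.
init_vae_params <- function(cfg) {
  D <- cfg$input_dim; h <- cfg$layersize; d <- cfg$latent_dim
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  list(
    W1 = he(D + 1, h), b1 = numeric(h),
    W2 = he(h, h),     b2 = numeric(h),
    Wmu = he(h, d) * 0.1, bmu = numeric(d),
    Wlv = he(h, d) * 0.1, blv = numeric(d),
    V1 = he(d, h), c1 = numeric(h),
    V2 = he(h, h), c2 = numeric(h),
    Vout = he(h, D) * 0.1, cout = numeric(D)
  )
}

new_vae_model <- function(cfg, params, history = NULL) {
  structure(list(config = cfg, params = params, history = history),
            class = "lols_vae")
}

#' @export
print.lols_vae <- function(x, ...) {
  cfg <- x$config
  cat("<lols_vae> D =", cfg$input_dim, " layersize =", cfg$layersize,
      " d =", cfg$latent_dim, " lambda =", cfg$lambda, " beta =", cfg$beta, "\n")
  if (!is.null(x$history)) {
    n <- nrow(x$history)
    cat("  trained", n, "epochs; final total loss",
        signif(x$history$total[n], 6), "\n")
  }
  invisible(x)
}

# Deterministic encoder pass on a batch (matrix X: N x D, Estar: length N).
encoder_forward <- function(params, X, Estar) {
  In <- cbind(X, Estar)
  H1 <- relu(sweep(In %*% params$W1, 2, params$b1, "+"))
  H2 <- relu(sweep(H1 %*% params$W2, 2, params$b2, "+"))
  mu <- sweep(H2 %*% params$Wmu, 2, params$bmu, "+")
  lv <- sweep(H2 %*% params$Wlv, 2, params$blv, "+")
  list(In = In, H1 = H1, H2 = H2, mu = mu, lv = lv)
}

decoder_forward <- function(params, Z) {
  G1 <- relu(sweep(Z %*% params$V1, 2, params$c1, "+"))
  G2 <- relu(sweep(G1 %*% params$V2, 2, params$c2, "+"))
  Xout <- sweep(G2 %*% params$Vout, 2, params$cout, "+")
  list(G1 = G1, G2 = G2, Xout = Xout)
}

#' Encode normalized dihedral records into the latent space
#'
#' Deterministic forward pass: the encoder input is the concatenation of the
#' normalized dihedral vector and the scaled energy.  After training, the
#' latent representation of a record is the mean `mu`; the variances are used
#' only for reparameterization during training.
#'
#' @param model A trained or initialized `lols_vae`.
#' @param x Normalized dihedral vector in `[-1, 1]^D`, or an N-by-D matrix.
#' @param E_star Scaled energy (scalar or length-N vector).
#' @return List with `mu` and `sigma2` (N-by-d matrices).
#' @export
encode <- function(model, x, E_star) {
  X <- rbind(x)
  if (ncol(X) != model$config$input_dim) abort("dimension mismatch in encode()")
  enc <- encoder_forward(model$params, X, as.numeric(E_star))
  list(mu = enc$mu, sigma2 = exp(enc$lv))
}

#' Decode latent vectors into normalized dihedral space
#'
#' @param model A `lols_vae`.
#' @param z Latent vector or N-by-d matrix.
#' @param clip Clip outputs into `[-1, 1]` (the decoder is unconstrained and
#'   may overshoot slightly); default `TRUE`.
#' @return N-by-D matrix of normalized dihedral vectors.
#' @export
decode <- function(model, z, clip = TRUE) {
  Z <- rbind(z)
  out <- decoder_forward(model$params, Z)$Xout
  if (clip) out <- pmin(pmax(out, -1), 1)
  out
}

#' Reparameterization draw
#'
#' `z = mu + sigma * eps` with `eps ~ N(0, I)`; used only during training —
#' after training, latent data points are `z = mu`.
#'
#' @param enc A `list(mu, sigma2)` as returned by [encode()].
#' @param seed Optional integer seed for the draw.
#' @return Matrix of latent samples, same shape as `enc$mu`.
#' @export
reparameterize <- function(enc, seed = NULL) {
  draw <- function() {
    eps <- matrix(stats::rnorm(length(enc$mu)), nrow(enc$mu), ncol(enc$mu))
    enc$mu + sqrt(enc$sigma2) * eps
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Closed-form KL divergence of the encoder posterior from the standard normal
#'
#' Mean over the batch of
#' `0.5 * sum_j (mu_j^2 + sigma_j^2 - 1 - ln sigma_j^2)`.
#'
#' @param mu N-by-d matrix of means (or a `list(mu, sigma2)`).
#' @param sigma2 N-by-d matrix of variances (positive).
#' @return Scalar `delta_kld` (>= 0).
#' @export
kl_divergence <- function(mu, sigma2 = NULL) {
  if (is.list(mu) && is.null(sigma2)) { sigma2 <- mu$sigma2; mu <- mu$mu }
  mu <- rbind(mu); sigma2 <- rbind(sigma2)
  if (any(sigma2 <= 0)) abort("sigma2 must be positive")
  mean(0.5 * rowSums(mu^2 + sigma2 - 1 - log(sigma2)))
}

#' Energy-weighted reconstruction loss
#'
#' `delta_rec = (1/N) * sum_i exp(beta * E*_i) * Diff_i`, where `Diff_i` is
#' the mean absolute difference over the D normalized dihedral components of
#' sample i.  Energies are not reconstructed and do not enter `Diff`.
#'
#' @param x_in,x_out N-by-D matrices of normalized dihedrals.
#' @param E_star Length-N scaled energies.
#' @param beta Energy weight (<= 0).
#' @return Scalar `delta_rec`.
#' @export
weighted_reconstruction_loss <- function(x_in, x_out, E_star, beta = 0) {
  x_in <- rbind(x_in); x_out <- rbind(x_out)
  if (!all(dim(x_in) == dim(x_out)) || nrow(x_in) != length(E_star)) {
    abort("batch length mismatch")
  }
  mean(exp(beta * E_star) * rowMeans(abs(x_in - x_out)))
}

#' Total VAE loss
#'
#' `delta_total = delta_rec + lambda * delta_kld`.
#'
#' @param delta_rec Reconstruction loss.
#' @param delta_kld KL divergence.
#' @param lambda Loss ratio; production default 0.01.
#' @return Scalar `delta_total`.
#' @export
total_loss <- function(delta_rec, delta_kld, lambda = 0.01) {
  delta_rec + lambda * delta_kld
}

#' Train the energy-weighted VAE
#'
#' Full-batch gradient training with Adam on `delta_total`.  Training stops
#' at `epochs` or earlier when the loss plateaus (best loss of the most
#' recent `patience`-epoch window improves on the preceding best by less
#' than `rtol` in relative terms).  Fully seeded and reproducible.
#'
#' @param x N-by-D matrix of normalized dihedrals (the `vae_included` subset
#'   of the pool).
#' @param E_star Length-N scaled energies.
#' @param config A [vae_config()].
#' @param init Optional `lols_vae` to warm-start from.
#' @return A trained `lols_vae`; `$history` holds the per-epoch loss table.
#' @export
train_vae <- function(x, E_star, config, init = NULL) {
  X <- rbind(x)
  N <- nrow(X); D <- ncol(X)
  if (N < 1) abort("empty training set")
  if (D != config$input_dim) abort("x does not match config$input_dim")
  cfg <- config
  withr::with_seed(cfg$seed, {
    p <- if (is.null(init)) init_vae_params(cfg) else init$params
    mst <- lapply(p, function(q) q * 0)
    vst <- lapply(p, function(q) q * 0)
    b1a <- 0.9; b2a <- 0.999; eps_a <- 1e-8; lr <- cfg$learning_rate
    w <- exp(cfg$beta * E_star)
    hist_total <- hist_rec <- hist_kld <- numeric(cfg$epochs)
    d <- cfg$latent_dim
    t_adam <- 0
    for (epoch in seq_len(cfg$epochs)) {
      enc <- encoder_forward(p, X, E_star)
      epsm <- matrix(stats::rnorm(N * d), N, d)
      sig <- exp(0.5 * enc$lv)
      Z <- enc$mu + sig * epsm
      dec <- decoder_forward(p, Z)

      diffs <- rowMeans(abs(X - dec$Xout))
      rec <- mean(w * diffs)
      s2 <- exp(enc$lv)
      kld <- mean(0.5 * rowSums(enc$mu^2 + s2 - 1 - enc$lv))
      hist_rec[epoch] <- rec; hist_kld[epoch] <- kld
      hist_total[epoch] <- rec + cfg$lambda * kld

      # ---- backward ----
      dXout <- (w / (N * D)) * sign(dec$Xout - X)
      g <- list()
      g$Vout <- crossprod(dec$G2, dXout); g$cout <- colSums(dXout)
      dA2 <- (dXout %*% t(p$Vout)) * (dec$G2 > 0)
      g$V2 <- crossprod(dec$G1, dA2); g$c2 <- colSums(dA2)
      dA1 <- (dA2 %*% t(p$V2)) * (dec$G1 > 0)
      g$V1 <- crossprod(Z, dA1); g$c1 <- colSums(dA1)
      dZ <- dA1 %*% t(p$V1)
      dmu <- dZ + (cfg$lambda / N) * enc$mu
      dlv <- dZ * epsm * 0.5 * sig + (cfg$lambda / (2 * N)) * (s2 - 1)
      g$Wmu <- crossprod(enc$H2, dmu); g$bmu <- colSums(dmu)
      g$Wlv <- crossprod(enc$H2, dlv); g$blv <- colSums(dlv)
      dB2 <- (dmu %*% t(p$Wmu) + dlv %*% t(p$Wlv)) * (enc$H2 > 0)
      g$W2 <- crossprod(enc$H1, dB2); g$b2 <- colSums(dB2)
      dB1 <- (dB2 %*% t(p$W2)) * (enc$H1 > 0)
      g$W1 <- crossprod(enc$In, dB1); g$b1 <- colSums(dB1)

      t_adam <- t_adam + 1
      bc1 <- 1 - b1a^t_adam; bc2 <- 1 - b2a^t_adam
      for (nm in names(p)) {
        mst[[nm]] <- b1a * mst[[nm]] + (1 - b1a) * g[[nm]]
        vst[[nm]] <- b2a * vst[[nm]] + (1 - b2a) * g[[nm]]^2
        p[[nm]] <- p[[nm]] - lr * (mst[[nm]] / bc1) /
          (sqrt(vst[[nm]] / bc2) + eps_a)
      }

      if (epoch %% cfg$patience == 0 && epoch >= 2 * cfg$patience) {
        recent <- min(hist_total[(epoch - cfg$patience + 1):epoch])
        before <- min(hist_total[1:(epoch - cfg$patience)])
        if (before - recent < cfg$rtol * max(abs(before), 1e-8)) break
      }
    }
    n_ep <- epoch
    history <- tibble(epoch = seq_len(n_ep),
                      rec = hist_rec[seq_len(n_ep)],
                      kld = hist_kld[seq_len(n_ep)],
                      total = hist_total[seq_len(n_ep)])
    new_vae_model(cfg, p, history)
  })
}

#' Reconstruction mean absolute error in degrees
#'
#' Deterministic pass (z = mu) of the records through the auto-encoder; the
#' mean absolute input-output difference over records and dimensions,
#' converted back to degrees using each dimension's range span.
#'
#' @param model A `lols_vae`.
#' @param x N-by-D matrix of normalized dihedrals.
#' @param E_star Length-N scaled energies.
#' @param ranges Optional ranges tibble; defaults to full 360-degree spans.
#' @return MAE in degrees.
#' @export
reconstruction_mae <- function(model, x, E_star, ranges = NULL) {
  X <- rbind(x)
  ranges <- as_ranges(ranges, ncol(X))
  enc <- encoder_forward(model$params, X, as.numeric(E_star))
  out <- decoder_forward(model$params, enc$mu)$Xout
  half_span <- (ranges$high - ranges$low) / 2
  mean(sweep(abs(X - out), 2, half_span, "*"))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy lols_vae
#' @export
tidy.lols_vae <- function(x, ...) x$history

#' @method glance lols_vae
#' @export
glance.lols_vae <- function(x, ...) {
  n <- nrow(x$history)
  tibble(epochs_run = n,
         delta_rec = x$history$rec[n],
         delta_kld = x$history$kld[n],
         delta_total = x$history$total[n],
         layersize = x$config$layersize,
         latent_dim = x$config$latent_dim,
         lambda = x$config$lambda,
         beta = x$config$beta)
}

#' Save/load a VAE checkpoint
#'
#' Self-describing JSON container holding the configuration and all weights.
#'
#' @param model A `lols_vae`.
#' @param path File path (`.json`).
#' @export
write_vae <- function(model, path) {
  payload <- list(config = unclass(model$config),
                  params = lapply(model$params, function(m) {
                    if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
                    else list(dim = NULL, data = as.numeric(m))
                  }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vae
#' @export
read_vae <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(vae_config, payload$config[c("input_dim", "layersize",
    "latent_dim", "lambda", "beta", "epochs", "learning_rate", "patience",
    "rtol", "seed")])
  params <- lapply(payload$params, function(e) {
    if (!is.null(e$dim) && length(e$dim)) matrix(e$data, e$dim[1], e$dim[2])
    else as.numeric(e$data)
  })
  new_vae_model(cfg, params)
}
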