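# Shared fixtures, built in code.

# Acyclic 8-atom carbon chain: 5 free backbone torsions.
chain8 <- chain_molecule(8)

# Small deterministic 2-D test surface with 4 wells.
pes2d <- make_synthetic_pes(dim = 2, n_wells = 4, seed = 7)

# Independent closed-form Gaussian KL oracle (kept separate from the
# package implementation on purpose).
kl_oracle <- function(mu, sigma2) {
  mean(vapply(seq_len(nrow(mu)), function(i) {
    0.5 * sum(mu[i, ]^2 + sigma2[i, ] - 1 - log(sigma2[i, ]))
  }, numeric(1)))
}

# Independent per-pair circular distance (scalar, one dimension).
circ1 <- function(a, b, span = 360) {
  d <- abs(a - b) %% span
  min(d, span - d)
}

angle_cols_vec <- function(D) paste0("angle_", seq_len(D))

# Vector of per-dimension circular absolute differences (span 360).
abs_circ <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Quick VAE config for unit tests: small net, short budget.
quick_vae <- function(D, seed = 1, ...) {
  vae_config(D, layersize = 24, epochs = 800, patience = 200, seed = seed, ...)
}
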