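test_that("KL divergence matches the closed-form Gaussian oracle", {
  expect_equal(kl_divergence(rbind(c(0, 0)), rbind(c(1, 1))), 0)
  expect_equal(kl_divergence(rbind(c(1, 0)), rbind(c(1, 1))), 0.5)
  set.seed(8)
  mu <- matrix(rnorm(2000), 1000, 2)
  s2 <- matrix(exp(rnorm(2000)), 1000, 2)
  expect_lt(abs(kl_divergence(mu, s2) - kl_oracle(mu, s2)), 1e-8)
  expect_gte(kl_divergence(mu, s2), 0)
  expect_error(kl_divergence(rbind(c(0, 0)), rbind(c(1, -1))), "positive")
})

test_that("the weighted reconstruction loss follows its closed form", {
  set.seed(3)
  x <- matrix(runif(50, -1, 1), 10, 5)
  y <- x + matrix(rnorm(50, 0, 0.1), 10, 5)
  es <- runif(10, 0, 3)
  # beta = 0: plain mean MAE
  expect_equal(weighted_reconstruction_loss(x, y, es, 0),
               mean(rowMeans(abs(x - y))), tolerance = 1e-12)
  # perfect reconstruction
  expect_equal(weighted_reconstruction_loss(x, x, es, -3), 0)
  # hand-computed two-sample case
  x2 <- rbind(rep(0, 5), rep(0, 5))
  y2 <- rbind(rep(0.2, 5), rep(0.2, 5))
  expect_equal(weighted_reconstruction_loss(x2, y2, c(0, log(2)), -1),
               (1 * 0.2 + 0.5 * 0.2) / 2)
  expect_error(weighted_reconstruction_loss(x, y[1:5, ], es, 0), "mismatch")
})

test_that("the total loss combines the two terms linearly", {
  expect_equal(total_loss(0.37, 2.2, 0), 0.37)
  expect_equal(total_loss(0.1, 2, 0.01), 0.12)
})

test_that("reparameterization is z = mu + sigma * eps", {
  enc <- list(mu = rbind(c(2, -1)), sigma2 = rbind(c(1e-30, 1e-30)))
  expect_equal(reparameterize(enc, seed = 1), rbind(c(2, -1)), tolerance = 1e-10)
  enc2 <- list(mu = rbind(c(0.5, -0.5)), sigma2 = rbind(c(0.04, 0.09)))
  expect_identical(reparameterize(enc2, seed = 7), reparameterize(enc2, seed = 7))
  # law of large numbers on the draw mean
  encN <- list(mu = matrix(1.5, 1e5, 1), sigma2 = matrix(0.25, 1e5, 1))
  zm <- mean(reparameterize(encN, seed = 2))
  expect_lt(abs(zm - 1.5), 4 * 0.5 / sqrt(1e5))
})

test_that("encoding is deterministic and shape-checked", {
  m <- train_vae(matrix(runif(40, -1, 1), 8, 5), runif(8), quick_vae(5))
  x <- matrix(runif(10, -1, 1), 2, 5)
  e1 <- encode(m, x, c(0.1, 0.2))
  e2 <- encode(m, x, c(0.1, 0.2))
  expect_identical(e1, e2)
  expect_true(all(e1$sigma2 > 0))
  expect_error(encode(m, matrix(0, 1, 3), 0), "dimension")
})

test_that("training is seeded-reproducible and its loss history is sane", {
  X <- matrix(runif(100, -1, 1), 20, 5)
  es <- runif(20, 0, 1)
  m1 <- train_vae(X, es, quick_vae(5, seed = 42))
  m2 <- train_vae(X, es, quick_vae(5, seed = 42))
  expect_identical(m1$params, m2$params)
  expect_true(all(is.finite(m1$history$total)))
  expect_true(all(diff(cummin(m1$history$total)) <= 0))
  expect_error(train_vae(X[0, , drop = FALSE], numeric(0), quick_vae(5)),
               "empty")
})

test_that("a single repeated point is reconstructed to within a degree", {
  x0 <- matrix(rep(0.3, 5), 1)
  m <- train_vae(x0, 0.1, vae_config(5, layersize = 32, epochs = 4000,
                                     patience = 4000, seed = 2))
  out <- decode(m, encode(m, x0, 0.1)$mu)
  expect_lt(max(abs(out - 0.3)) * 180, 1)
})

test_that("well-separated clusters are reconstructed within 20 degrees", {
  maes <- sapply(1:3, function(s) {
    set.seed(100 + s)
    centers <- matrix(runif(20, -0.8, 0.8), 4, 5)
    X <- centers[rep(1:4, each = 100), ] +
      matrix(rnorm(2000, 0, 0.03), 400, 5)
    X <- pmin(pmax(X, -1), 1)
    es <- runif(400, 0, 0.3)
    m <- train_vae(X, es, vae_config(5, layersize = 80, epochs = 1500,
                                     patience = 300, seed = s))
    reconstruction_mae(m, X, es)
  })
  expect_lte(median(maes), 20)
})

test_that("the reconstruction MAE has the right scale and symmetries", {
  m <- train_vae(matrix(runif(40, -1, 1), 8, 5), runif(8), quick_vae(5))
  # constant-zero decoder: outputs are identically 0
  m$params$V1[] <- 0; m$params$V2[] <- 0; m$params$Vout[] <- 0
  m$params$c1[] <- 0; m$params$c2[] <- 0; m$params$cout[] <- 0
  set.seed(14)
  X <- matrix(runif(4000 * 5, -1, 1), 4000, 5)
  es <- rep(0, 4000)
  # E|U(-1,1)| = 0.5 in normalized units = 90 degrees
  expect_equal(reconstruction_mae(m, X, es), 90, tolerance = 1.5)
  perm <- sample(4000)
  expect_equal(reconstruction_mae(m, X[perm, ], es[perm]),
               reconstruction_mae(m, X, es))
})

test_that("negative beta down-weights high-energy samples monotonically", {
  x <- matrix(0, 4, 3)
  y <- matrix(0.2, 4, 3)
  es <- c(0.1, 0.5, 1, 2)
  for (i in 1:4) {
    es2 <- es
    es2[i] <- es[i] + 0.5
    expect_lt(weighted_reconstruction_loss(x, y, es2, -1),
              weighted_reconstruction_loss(x, y, es, -1))
  }
})

test_that("a VAE checkpoint round-trips through JSON", {
  m <- train_vae(matrix(runif(40, -1, 1), 8, 5), runif(8), quick_vae(5))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_vae(m, tmp)
  m2 <- read_vae(tmp)
  x <- matrix(runif(10, -1, 1), 2, 5)
  expect_equal(encode(m2, x, c(0, 0.1)), encode(m, x, c(0, 0.1)),
               tolerance = 1e-12)
})
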