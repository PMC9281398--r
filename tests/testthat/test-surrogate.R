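# A moderately sized shared fit: 2-D surface, 300 training points.
local({
  be <- synthetic_backend(pes2d)
  pool300 <<- generate_initial_data(be, 300, seed = 2)
  gp300 <<- fit_energy_model(pool300)
})

test_that("the energy model interpolates its training data", {
  pr <- predict_energy(gp300, as.matrix(pool300[, 1:2]))
  resid <- abs(pr$mean - pool300$scaled_energy)
  expect_true(all(resid <= 3 * (gp300$noise + pr$sd) + 1e-6))
})

test_that("predictions recover a known periodic surface within 5% of range", {
  g <- as.matrix(expand.grid(seq(0, 345, 15), seq(0, 345, 15)))
  truth <- scale_energy(pes_energy(pes2d, g), attr(pool300, "E0"))
  pr <- predict_energy(gp300, g)
  rmse <- sqrt(mean((pr$mean - truth)^2))
  expect_lt(rmse, 0.05 * diff(range(truth)))
})

test_that("predictions are periodic in every dimension", {
  set.seed(3)
  X <- matrix(runif(20, 0, 360), 10, 2)
  p0 <- predict_energy(gp300, X)$mean
  p1 <- predict_energy(gp300, X + 360)$mean
  p2 <- predict_energy(gp300, sweep(X, 2, c(360, -720), "+"))$mean
  expect_lt(max(abs(p0 - p1)), 1e-8)
  expect_lt(max(abs(p0 - p2)), 1e-8)
})

test_that("the posterior reverts to the prior mean far from data", {
  # data confined to a small patch
  patch <- pool300[1:40, ]
  patch[, 1] <- 100 + runif(40, -8, 8)
  patch[, 2] <- 100 + runif(40, -8, 8)
  gp <- fit_energy_model(patch)
  far <- predict_energy(gp, c(280, 280))
  expect_lt(abs(far$mean - gp$mean), 0.1 * diff(range(patch$scaled_energy)) + 0.02)
  # variance shrinks at the data
  near <- predict_energy(gp, as.matrix(patch[1, 1:2]))
  expect_lt(near$sd, far$sd)
})

test_that("the posterior-mean gradient matches finite differences", {
  set.seed(4)
  for (i in 1:10) {
    x <- runif(2, 0, 360)
    g <- lols:::posterior_mean_grad(gp300, x)
    fd <- sapply(1:2, function(j) {
      xp <- x; xm <- x; xp[j] <- xp[j] + 1e-4; xm[j] <- xm[j] - 1e-4
      (lols:::posterior_mean(gp300, xp) - lols:::posterior_mean(gp300, xm)) / 2e-4
    })
    expect_lt(max(abs(g - fd)) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("extracted minima reproduce the brute-force oracle", {
  oracle <- bruteforce_minima(pes2d, 24)
  mins <- merge_similar(extract_local_minima(gp300))
  expect_equal(nrow(mins), nrow(oracle))
  for (i in seq_len(nrow(oracle))) {
    d <- apply(as.matrix(mins[, 1:2]), 1, function(a) {
      dihedral_distance(a, as.numeric(oracle[i, 1:2]))["mean"]
    })
    expect_lt(min(d), 5)
  }
  # starting exactly at a minimum returns that point
  m1 <- extract_local_minima(gp300, starts = as.matrix(mins[1, 1:2]))
  expect_lt(dihedral_distance(as.numeric(m1[1, 1:2]),
                              as.numeric(mins[1, 1:2]))["mean"], 0.5)
})

test_that("a single-basin model yields a single merged minimum", {
  pes1 <- make_synthetic_pes(dim = 2, n_wells = 1, seed = 5)
  be <- synthetic_backend(pes1)
  pool <- generate_initial_data(be, 150, seed = 3)
  gp <- fit_energy_model(pool)
  mins <- merge_similar(extract_local_minima(gp))
  expect_equal(nrow(mins), 1)
})

test_that("fitting raw E and scaled E* give the same minima locations", {
  gp_raw <- fit_energy_model(pool300, target = "raw")
  m_scaled <- merge_similar(extract_local_minima(gp300))
  m_raw <- merge_similar(extract_local_minima(gp_raw))
  expect_equal(nrow(m_scaled), nrow(m_raw))
  for (i in seq_len(nrow(m_scaled))) {
    d <- apply(as.matrix(m_raw[, 1:2]), 1, function(a) {
      max(abs_circ(a, as.numeric(m_scaled[i, 1:2])))
    })
    expect_lt(min(d), 2)
  }
})

test_that("duplicate purging keeps the lowest-energy member per group", {
  cand <- tibble::tibble(angle_1 = c(10, 20, 100), angle_2 = c(10, 20, 100),
                         energy = c(0.01, 0.00, 0.05))
  out <- merge_similar(cand)
  expect_equal(nrow(out), 2)
  expect_equal(out$energy[1], 0)                 # 10-degree pair collapsed
  expect_equal(out$angle_1[1], 20)
  cand2 <- tibble::tibble(angle_1 = c(0, 20), angle_2 = c(0, 20),
                          energy = c(0, 0.01))
  expect_equal(nrow(merge_similar(cand2)), 2)    # mean diff 20: both kept
  expect_identical(merge_similar(out), out)      # idempotent
  # circular wrap: 359 vs 1 are 2 degrees apart
  cand3 <- tibble::tibble(angle_1 = c(359, 1), angle_2 = c(180, 181),
                          energy = c(0.2, 0.1))
  expect_equal(nrow(merge_similar(cand3)), 1)
})

test_that("the fit refuses underdetermined pools and degenerate data warns", {
  tiny <- pool300[1:3, ]
  expect_error(fit_energy_model(tiny), "2\\*D")
  dup <- pool300[rep(1, 30), ]
  expect_no_error(fit_energy_model(dup))
})
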