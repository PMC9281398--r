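test_that("surface construction is deterministic per seed", {
  p1 <- make_synthetic_pes(2, 3, seed = 7)
  p2 <- make_synthetic_pes(2, 3, seed = 7)
  expect_identical(p1$wells, p2$wells)
  expect_identical(p1$pairs, p2$pairs)
  p3 <- make_synthetic_pes(2, 3, seed = 8)
  expect_false(identical(p1$wells, p3$wells))
})

test_that("an uncoupled surface is separable: minima are the product set", {
  pes <- make_synthetic_pes(dim = 2, n_wells = 6, coupling_strength = 0,
                            seed = 3)
  # independent 1-D oracle: fine-grid argmin per dimension, then polish
  per_dim <- lapply(1:2, function(j) {
    g <- seq(0, 359.9, 0.1)
    w <- pes$wells[[j]]
    prof <- w$A / 2 * (1 - cos(w$k * (g - w$phase) * pi / 180)) +
      w$b / 2 * (1 - cos((g - w$psi) * pi / 180))
    is_min <- prof < c(prof[-1], prof[1]) & prof < c(prof[length(prof)], prof[-length(prof)])
    g[is_min]
  })
  prod_pts <- expand.grid(per_dim)
  m <- bruteforce_minima(pes, 36)
  expect_equal(nrow(m), nrow(prod_pts))
  for (i in seq_len(nrow(prod_pts))) {
    d <- apply(as.matrix(m[, 1:2]), 1, function(a) {
      dihedral_distance(a, as.numeric(prod_pts[i, ]))["mean"]
    })
    expect_lt(min(d), 1)
  }
})

test_that("the 5-D benchmark surface has an oracle-countable set of minima", {
  pes <- make_synthetic_pes(dim = 5, n_wells = 10, seed = 1)
  m <- bruteforce_minima(pes, 24)
  expect_gte(nrow(m), 5)
  expect_lte(nrow(m), 20)
  # unique global minimum separated by at least 5 meV
  expect_gte(m$energy[2] - m$energy[1], 0.005)
  # polished minima are stationary
  for (i in seq_len(nrow(m))) {
    g <- pes_gradient(pes, as.numeric(m[i, angle_cols_vec(5)]))
    expect_lte(sqrt(sum(g^2)), 1e-6)
  }
})

test_that("the surface is periodic and its gradient matches finite differences", {
  # zero offset for the difference quotient: a -2e4 eV base drowns the
  # O(eps*|E|/h) cancellation error of central differences
  pes <- make_synthetic_pes(dim = 3, n_wells = 6, seed = 4, base_energy = 0)
  set.seed(5)
  for (i in 1:20) {
    x <- runif(3, 0, 360)
    expect_lt(abs(pes_energy(pes, x) - pes_energy(pes, x + c(360, -360, 720))),
              1e-10)
    g <- pes_gradient(pes, x)
    fd <- sapply(1:3, function(j) {
      xp <- x; xm <- x; xp[j] <- xp[j] + 1e-5; xm[j] <- xm[j] - 1e-5
      (pes_energy(pes, xp) - pes_energy(pes, xm)) / 2e-5
    })
    expect_lt(max(abs(g - fd)), 1e-7)
  }
})

test_that("the oracle global minimum beats a dense random probe", {
  pes <- make_synthetic_pes(dim = 3, n_wells = 8, seed = 12)
  m <- bruteforce_minima(pes, 24)
  set.seed(1)
  probe <- matrix(runif(3e4, 0, 360), 1e4, 3)
  expect_lte(m$energy[1], min(pes_energy(pes, probe)))
})

test_that("oracle minima are stable under grid refinement", {
  for (dd in 2:3) {
    pes <- make_synthetic_pes(dim = dd, n_wells = 4, seed = 9)
    m1 <- bruteforce_minima(pes, 24)
    m2 <- bruteforce_minima(pes, 36)
    expect_equal(nrow(m1), nrow(m2))
    for (i in seq_len(nrow(m1))) {
      d <- sapply(seq_len(nrow(m2)), function(j) {
        max(abs_circ(as.numeric(m1[i, angle_cols_vec(dd)]),
                     as.numeric(m2[j, angle_cols_vec(dd)])))
      })
      expect_lt(min(d), 2)
    }
  }
})

test_that("backends evaluate conformations and surface files round-trip", {
  pes <- make_synthetic_pes(dim = 2, n_wells = 4, seed = 7)
  be <- synthetic_backend(pes)
  x <- c(100, 250)
  expect_equal(evaluate_energy(be, x), pes_energy(pes, x))
  expect_equal(evaluate_energy(be, conformation(x)), pes_energy(pes, x))
  cb <- callable_backend(function(a) sum(a), dim = 2)
  expect_equal(evaluate_energy(cb, c(10, 20)), 30)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_pes(pes, tmp)
  pes2 <- read_pes(tmp)
  set.seed(2)
  X <- matrix(runif(20, 0, 360), 10, 2)
  expect_equal(pes_energy(pes2, X), pes_energy(pes, X), tolerance = 1e-12)
})

test_that("the external-engine stub parses an energy and flags failures", {
  spec <- chain_molecule(5)
  sh <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo 'total energy: -19635.25 eV'"), sh)
  Sys.chmod(sh, "0755")
  be <- external_backend(paste(sh, "{xyz}"), spec)
  expect_equal(evaluate_energy(be, c(180, 180)), -19635.25)
  bad <- external_backend("false {xyz}", spec)
  expect_true(is.na(evaluate_energy(bad, c(180, 180))))
})

test_that("clash screening marks invalid conformations before evaluation", {
  # chain folded onto itself: tight clash scale flags nothing at reference
  spec <- chain_molecule(6)
  pes <- make_synthetic_pes(dim = 3, n_wells = 3, seed = 2)
  be <- with_molecule(synthetic_backend(pes), spec, clash_scale = 0.7)
  expect_false(is.na(evaluate_energy(be, c(180, 180, 180))))
  # gauche-gauche folds bring terminal atoms close; with an absurdly large
  # clash scale every conformation is invalid
  be2 <- with_molecule(synthetic_backend(pes), spec, clash_scale = 3)
  expect_true(is.na(evaluate_energy(be2, c(180, 180, 180))))
})
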