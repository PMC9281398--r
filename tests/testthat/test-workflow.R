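# Shared small end-to-end run on the 2-D fixture surface.
local({
  be2 <<- synthetic_backend(pes2d)
  oracle2 <<- bruteforce_minima(pes2d, 24)
  targets2 <<- dplyr::filter(oracle2, rel_energy <= 0.25)
  cfg_small <<- lols_config(initdata = 50, M = 4, k = 2, batch_size = 20,
                            beta = -1, layersize = 24, epochs = 600,
                            patience = 150, seed = 11)
  run_small <<- run_lols(be2, cfg_small)
})

test_that("initial data is valid, in range and seeded", {
  pool <- generate_initial_data(be2, 30, seed = 5)
  expect_equal(nrow(pool), 30)
  A <- as.matrix(pool[, 1:2])
  expect_true(all(A >= 0 & A <= 360))
  expect_false(any(is.na(pool$energy_eV)))
  pool2 <- generate_initial_data(be2, 30, seed = 5)
  expect_identical(as.data.frame(pool), as.data.frame(pool2))
  expect_equal(attr(pool, "attempts"), 30)  # no invalid draws on a bare surface
})

test_that("the loop keeps exact sample accounting and banks every model", {
  cfg <- cfg_small
  expect_equal(nrow(run_small$pool),
               cfg$initdata + cfg$M * cfg$batch_size - run_small$invalid)
  # energy models at iterations k, 2k, ..., M
  expect_equal(sort(unique(run_small$bank$model_index)), c(2, 4))
  expect_equal(run_small$counts$relax, nrow(run_small$bank))
  # conformer list is sorted with non-negative relative energies
  expect_true(all(diff(run_small$conformers$energy_eV) >= 0))
  expect_true(all(run_small$conformers$rel_energy >= 0))
  expect_equal(min(run_small$conformers$rel_energy), 0)
})

test_that("identical config and seed reproduce the run exactly", {
  again <- run_lols(be2, cfg_small)
  expect_identical(as.data.frame(again$conformers),
                   as.data.frame(run_small$conformers))
  expect_identical(again$counts, run_small$counts)
})

test_that("the small run recovers the oracle conformers of the 2-D surface", {
  rep2 <- match_targets(run_small$conformers, targets2)
  expect_true(rep2$global_min_achieved)
  expect_gte(rep2$frac_achieved, 0.7)
})

test_that("latent snapshots are recorded per iteration", {
  expect_setequal(unique(run_small$latent$iteration), 1:4)
  expect_true(all(is.finite(run_small$latent$z1)))
})

test_that("target matching applies the max-difference rule", {
  targets <- tibble::tibble(angle_1 = 100, angle_2 = 200, rel_energy = 0.3)
  hit <- tibble::tibble(angle_1 = 114, angle_2 = 214, rel_energy = 0.1)
  rep1 <- match_targets(hit, targets)
  expect_true(rep1$targets$achieved[1])
  # mean below 15 but one dimension at 16: not achieved
  miss <- tibble::tibble(angle_1 = 100, angle_2 = 216, rel_energy = 0.1)
  rep2 <- match_targets(miss, targets)
  expect_false(rep2$targets$achieved[1])
  expect_true(rep2$results$is_new[1])
  # circular wrap counts
  wrap <- tibble::tibble(angle_1 = 352, angle_2 = 200, rel_energy = 0.1)
  t2 <- tibble::tibble(angle_1 = 2, angle_2 = 200, rel_energy = 0)
  expect_true(match_targets(wrap, t2)$targets$achieved[1])
  # empty target list: everything is new
  rep3 <- match_targets(hit, targets[0, ])
  expect_true(all(rep3$results$is_new))
  expect_equal(rep3$n_achieved, 0L)
})

test_that("results above the highest target energy are not counted as new", {
  targets <- tibble::tibble(angle_1 = c(100, 300), angle_2 = c(100, 300),
                            rel_energy = c(0, 0.2))
  res <- tibble::tibble(angle_1 = c(200, 201), angle_2 = c(200, 201),
                        rel_energy = c(0.1, 0.5))
  rep <- match_targets(res, targets)
  expect_identical(rep$results$is_new, c(TRUE, FALSE))
})

test_that("the stopping rule needs the global minimum plus 70% coverage", {
  mk <- function(n_ach, gm) {
    list(targets = tibble::tibble(rel_energy = seq(0, 1, length.out = 11)),
         n_achieved = n_ach, frac_achieved = n_ach / 11,
         global_min_achieved = gm)
  }
  expect_true(stop_check(mk(8, TRUE)))    # 8/11 >= 0.7 with the global min
  expect_false(stop_check(mk(7, TRUE)))   # 7/11 < 0.7
  expect_false(stop_check(mk(10, FALSE))) # global minimum missed
  expect_false(stop_check(list(targets = NULL, global_min_achieved = NA)))
})

test_that("refinement converges instantly from a true minimum", {
  x0 <- as.numeric(oracle2[1, 1:2])
  cand <- tibble::tibble(angle_1 = x0[1], angle_2 = x0[2], energy = 0)
  out <- refine_candidates(cand, be2)
  expect_equal(out$converged, 1L)
  expect_lt(abs(out$conformers$energy_eV[1] - oracle2$energy[1]), 1e-8)
})

test_that("the real-space baseline shares the pipeline and its accounting", {
  cfg <- lols_config(initdata = 60, M = 4, k = 2, batch_size = 40, seed = 21)
  base <- run_real_space_baseline(be2, cfg)
  expect_equal(nrow(base$pool), 60 + 4 * 40 - base$invalid)
  expect_equal(base$counts$single, 60 + 4 * 40)
  rep <- match_targets(base$conformers, oracle2)
  expect_equal(rep$n_achieved, nrow(oracle2))  # 220 samples resolve 4 wells
  base2 <- run_real_space_baseline(be2, cfg)
  expect_identical(as.data.frame(base2$conformers), as.data.frame(base$conformers))
})

test_that("parallel-run merging never loses achieved targets", {
  cfgB <- lols_config(initdata = 50, M = 2, k = 2, batch_size = 20,
                      beta = -1, layersize = 24, epochs = 400,
                      patience = 100, seed = 31)
  runB <- run_lols(be2, cfgB)
  merged <- merge_runs(list(run_small, runB))
  n_m <- match_targets(merged$conformers, targets2)$n_achieved
  n_a <- match_targets(run_small$conformers, targets2)$n_achieved
  n_b <- match_targets(runB$conformers, targets2)$n_achieved
  expect_gte(n_m, max(n_a, n_b))
  expect_equal(merged$counts$single,
               run_small$counts$single + runB$counts$single)
})

test_that("the achievement curve is non-decreasing by candidate banking", {
  cfg <- lols_config(initdata = 50, M = 4, k = 2, batch_size = 20,
                     beta = -1, layersize = 24, epochs = 500,
                     patience = 150, seed = 41, stop_frac = 1.1)
  run <- run_lols(be2, cfg, targets = targets2)
  expect_true(all(diff(run$curve$achieved) >= 0))
})

test_that("latent island mapping handles the degenerate decoders", {
  m <- train_vae(matrix(runif(40, -1, 1), 8, 5), runif(8), quick_vae(5))
  target <- tibble::tibble(angle_1 = 180, angle_2 = 180, angle_3 = 180,
                           angle_4 = 180, angle_5 = 180, rel_energy = 0)
  # constant decoder emitting exactly the target
  m$params$V1[] <- 0; m$params$V2[] <- 0; m$params$Vout[] <- 0
  m$params$c1[] <- 0; m$params$c2[] <- 0
  m$params$cout <- rep(0, 5)   # normalized 0 = 180 degrees
  z <- matrix(rnorm(40), 20, 2)
  isl <- map_latent_islands(m, z, target, grid_n = 25)
  expect_equal(isl$areas$area_fraction, 1)
  expect_equal(isl$total_area_fraction, 1)
  # a far-away target claims nothing
  far <- dplyr::mutate(target, angle_1 = 0, angle_2 = 0, angle_3 = 0,
                       angle_4 = 0, angle_5 = 0)
  isl2 <- map_latent_islands(m, z, far, grid_n = 25)
  expect_equal(isl2$total_area_fraction, 0)
  # area fractions can never exceed one in total
  expect_lte(sum(isl$areas$area_fraction), 1)
})

test_that("run artifacts export to disk", {
  dir <- withr::local_tempdir()
  write_run(run_small, dir)
  expect_true(file.exists(file.path(dir, "conformers.tsv")))
  expect_true(file.exists(file.path(dir, "pool.tsv")))
  expect_true(file.exists(file.path(dir, "report.json")))
  rep <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(rep$counts$single, run_small$counts$single)
})
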