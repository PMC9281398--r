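# lols

Low-energy latent-space conformer search for flexible molecules, in R.

## The problem

Any molecule with rotatable bonds adopts many energetically accessible
conformers, and finding the low-energy ones with quantum-mechanical accuracy
is a long-standing bottleneck: the torsional search space grows exponentially
with the number of rotatable bonds, while every energy evaluation at the
reference level is expensive. `lols` implements an active-learning search
that works in the reduced space of dihedral angles **x** (degrees), keeping
bond lengths and angles fixed until the final refinement step.

## The method

One search iterates three coupled models:

1. **Energy-weighted VAE.** An encoder maps `(x, E*)` — normalized dihedrals
   plus the scaled energy — through two ReLU layers onto a diagonal Gaussian
   `N(mu, sigma^2)` in a 2-D latent space; a mirror-image decoder maps latent
   points back to dihedrals. The loss is

   `delta_total = delta_rec + lambda * delta_kld`,
   `delta_rec = (1/N) sum_i exp(beta * E*_i) * Diff(x_i_in, x_i_out)`,

   with `Diff` the mean absolute difference of the normalized dihedrals and
   `delta_kld` the closed-form KL divergence from the standard normal. A
   negative energy weight `beta` down-weights high-energy structures so the
   latent space preferentially encodes the low-energy part of the surface.
   Energies are scaled by `E* = E - E0` below the threshold `E0` and
   `ln(1 + E - E0)` above it, and records with
   `E* > mean(E*) + alpha * sd(E*)` are excluded from VAE training (but kept
   for the energy model).

2. **Latent rectangle sampling.** After each retraining the pool is encoded
   (`z = mu`), the minimal bounding rectangle of the latent points is
   expanded by 20%, and a batch of uniform draws is decoded, evaluated on
   the energy backend and appended to the pool.

3. **Periodic-kernel GP energy model.** Every `k` iterations a Gaussian
   process with a standard periodic (exp-sine-squared) kernel per torsion,
   fixed observation noise (0.001 eV) and inverse-gamma lengthscale priors
   is fitted to the whole pool. Local minima of the posterior mean are
   collected by conjugate-gradient descent from every training point,
   deduplicated (mean circular dihedral distance < 15 degrees, keeping the
   lowest energy), banked across all model fits, refined on the true
   backend energy at the end, and ranked.

The energy backend is pluggable: a built-in synthetic periodic multi-well
surface whose minima can be enumerated exactly by brute force (the test
oracle), any R function, or a templated external program.

## Worked example

```r
library(lols)

pes     <- make_synthetic_pes(dim = 2, n_wells = 4, seed = 7)
backend <- synthetic_backend(pes)
oracle  <- bruteforce_minima(pes, grid_points_per_dim = 24)
targets <- dplyr::filter(oracle, rel_energy <= 0.25)

cfg <- lols_config(initdata = 50, M = 4, k = 2, batch_size = 20,
                   beta = -1, layersize = 24, epochs = 600,
                   patience = 150, seed = 11)
run <- run_lols(backend, cfg, targets = targets)
run
#> <lols_run> run 1 : pool 90 records, 4 conformer(s)
#>   single: 90  relax: 4  converged: 4  invalid: 0
#>   early stop at iteration 2

run$conformers
#> # A tibble: 4 x 7
#>   angle_1 angle_2 energy_eV model_index run_id converged rel_energy
#>     <dbl>   <dbl>     <dbl>       <int>  <int> <lgl>          <dbl>
#> 1    143.    286.   -20000.           2      1 TRUE          0
#> 2    324.    284.   -20000.           2      1 TRUE          0.0391
#> 3    144.    104.   -20000.           2      1 TRUE          0.0457
#> 4    323.    106.   -20000.           2      1 TRUE          0.0636
```

The run stopped early because the banked minima already contained the global
minimum and more than 70% of the reference targets. The four refined
conformers coincide with the brute-force oracle of this surface: the same
count, the same torsion angles within a fraction of a degree, and relative
energies (`rel_energy`, eV above the global minimum) matching the oracle's
ladder. `single` counts single-point energy evaluations, `relax` the
candidates refined, `converged` those meeting the force tolerance within the
step limit.

`tidy(run)` returns the conformer table, `glance(run)` the bookkeeping
summary, `autoplot(run)` the energy ladder and `plot_latent(run)` the
encoded pool. A thin command-line front end is included at
`inst/cli/lols.R` (`make-pes`, `run`, `baseline`, `refine`, `match`,
`analyze-latent`).

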