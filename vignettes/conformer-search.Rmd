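---
title: "Low-energy latent-space conformer search: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-energy latent-space conformer search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lols)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, and the design
decisions taken where a published description leaves the implementer
freedom. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The search problem and its representation

A flexible molecule is represented as a rigid skeleton (reference Cartesian
geometry, bond lengths and angles frozen) plus an ordered list of `D`
rotatable dihedrals, each with a declared range and periodicity
(`molecule_spec()`). Dihedrals with a symmetry-halved search range (e.g.
a phenyl rotation searched on `[0, 180]`) are treated as periodic with span
equal to the range length in every distance and kernel computation. Atom
indices are 0-based at all interfaces; angles are degrees everywhere.

Torsion driving (`apply_dihedrals()`) rotates, for each dihedral
`(a, b, c, d)`, the rigid subtree on the `d` side of the `b`–`c` bond; the
partition is computed once from the bond graph, which is inferred from the
reference geometry by a covalent-radius criterion (factor 1.2, overridable).
Bonds inside rings are rejected — ring torsions are out of scope. The sign
convention is fixed by the standard four-point `atan2` torsion (trans =
180 degrees); only round-trip consistency matters, and the suite verifies
`measure(apply(x)) = x` to `1e-6` degrees on acyclic fixtures.

Structures whose non-bonded atoms approach closer than `0.7` times the sum
of their covalent radii are flagged invalid and never enter the data pool.
The 0.7 factor stands in for the behaviour of quantum-chemistry codes,
which simply fail to converge on sterically clashed geometries; it is a
package constant because no algorithmic criterion is published for that
failure.

## Preprocessing

Dihedrals are mapped linearly from their ranges onto `[-1, 1]`. Raw
energies `E` (eV) are scaled relative to a per-molecule threshold `E0`:

$$E^* = \begin{cases} E - E_0, & E \le E_0\\ \ln(1 + E - E_0), & E > E_0\end{cases}$$

The published description fixes the qualitative shape of this map — anchored
at zero near `E0`, strictly increasing, logarithmically compressing above
`E0` — but not its closed form; the piecewise form above is this package's
transcription and satisfies every stated property (continuity, C1 at the
threshold, increments above `E0` never exceeding raw increments). Because
the map is monotone, the argmin of `E` and `E*` coincide, so minima
locations do not depend on which is fitted; the suite asserts this both
directly and through the energy model. `E0` is held fixed per system; for
synthetic backends it defaults to the minimum energy of the initial data.
Raw `E` is the source of truth: `E*` is recomputed whenever `E0` changes.

Records with `E* > mean(E*) + alpha * sd(E*)` are excluded from VAE
training but kept in the pool for the energy model. Two details are not
published and were fixed here: the standard deviation is the population
(not sample) one, and the inequality is strict, so records exactly at the
threshold are retained. The default `alpha = 2` is the production value.

## The energy-weighted VAE

Encoder: input `(x, E*)` of length `D + 1`, two fully connected ReLU
layers of `layersize` neurons, linear heads for the mean and log-variance
of a `d`-dimensional diagonal Gaussian (`d = 2` by default; higher `d` is
plumbed through but untested). The log-variance head guarantees positive
`sigma^2` — an architecture detail the published description omits.
Decoder: mirror image, emitting dihedrals only; energies are not
reconstructed. During training `z = mu + sigma * eps`; after training the
latent representation of a record is `z = mu`.

The loss is `delta_rec + lambda * delta_kld` with

$$\delta_{rec} = \frac{1}{N}\sum_i e^{\beta E^*_i}\,
\mathrm{Diff}(x_i^{in}, x_i^{out}), \qquad
\mathrm{Diff} = \frac{1}{D}\sum_j |x_{ij}^{in} - x_{ij}^{out}|$$

and `delta_kld` the closed-form Gaussian KL from the standard normal,
averaged over the batch. The weight uses the raw stored `E*` without any
batch-level shift, exactly as printed in the source description. `Diff`
is deliberately non-circular (it acts on normalized values as printed);
periodicity is honoured only in dihedral-space distances. Defaults:
`lambda = 0.01` (the production value; the latent-scale diagnostic below
motivates it), `beta` in `{0, -1, -3}` with `-1` as the loop default,
`layersize` 80 for 5-D searches and 128 for 7–9-D.

Training is full-batch Adam (learning rate `1e-3`): pools are at most a
few thousand records, so full batches are cheaper and noise-free, and the
optimizer/batching regime is not specified in the published description.
Training stops at the epoch budget or earlier when the running-best loss
over the most recent `patience` epochs improves on the preceding best by
less than `rtol = 1e-5` relatively. Two budgets exist because the
published account is ambiguous (a convergence study quotes 100,000 epochs
while the general parameter table lists 100): standalone `train_vae()`
defaults to 100,000 epochs with the plateau rule, while the in-loop
retraining budget (`lols_config(epochs = 2000, patience = 200)`) reflects
that each retraining starts close to a previous optimum in data space and
plateaus quickly; the general table's small printed value indicates the
original loop likewise used a far smaller per-iteration budget. Each
retraining re-initializes the network from a seed derived from (run seed,
iteration) — restarts average out initialization pathologies, and warm
starting is available as a flag (`warm_start`).

## Latent-space scale and rectangle sampling

The latent-space scale `L` summarizes the spread of the encoded training
data. Its published definition is also figure-rendered; this package uses
the root-mean-square distance of the latent points about their centroid,
which satisfies the two properties the description pins down: `L = 0` for
a collapsed cloud, and dilating the cloud about its centroid by `c` scales
`L` by `c`. `L` is stable across `lambda` in the usable region (the suite
sweeps `lambda` over `[0.003, 0.03]` on a clustered fixture and bounds the
ratio), which is the diagnostic for choosing `lambda`.

Sampling draws `batch_size` (default 50) points uniformly from the minimal
axis-aligned bounding box of the latent data, expanded symmetrically about
its center by `expansion_rate` (default 20%) — the published figure shows a
centered extension, the anchoring is not stated. Two degenerate-input
rules are package decisions: a collapsed (zero-width) side is opened by an
absolute 0.1 on each end so sampling never degenerates to a point, and
decoder outputs are clipped to `[-1, 1]` before denormalization so every
decoded structure lies inside its declared ranges. Invalid (clashing)
decoded samples are dropped without replacement draws, and a backend
failure rate above 50% in one iteration aborts the run.

## The energy model

The surrogate is a Gaussian process on the (scaled) energies over
dihedral space with a product of standard periodic (exp-sine-squared)
kernels,

$$k(x, x') = \sigma_f^2 \prod_j \exp\!\big(-2\sin^2(\pi \Delta_j / p_j)/\ell_j^2\big),$$

with `p_j` the range span of torsion `j`. The published description names
the kernel family but not its parameterization; the standard form above is
used. Observation noise is fixed at 0.001 eV. Hyperparameters are chosen
by maximizing the marginal likelihood plus inverse-gamma log-priors on the
lengthscales (shape 2, scale 1, concentrating angular lengthscales roughly
in the 5–120 degree band), from two deterministic starts. The GP mean is
the empirical mean of the targets — a flat, data-driven choice standing in
for "uninformative". The model is fitted to `E*` by default; fitting raw
`E` is supported and the suite shows minima locations agree within
2 degrees.

Minima extraction runs conjugate-gradient descent of the posterior mean
from every training input (subsampled to 5,000 starts for very large
pools), using the analytic kernel gradient. Coordinates are wrapped into
their periodic spans rather than box-constrained — torsions are circular.
`optim`'s `parscale` is set to an eighth of the period: degree-scaled
coordinates with eV-scaled gradients otherwise stall first-order methods.
Endpoints must reach a gradient norm of `1e-5` eV/degree (one BFGS polish
is attempted first); failing starts are skipped with a message.
Deduplication is single-linkage grouping under mean circular dihedral
distance below 15 degrees, keeping each group's lowest-energy member, with
exact ties broken by lexicographic angle order for determinism.

## The synthetic benchmark surface

The generator stands in for a quantum-chemistry backend and defines the
study conditions of the test suite. Each dimension carries the familiar
cosine-series torsional profile

$$V_j(\theta) = \tfrac{A_j}{2}\big(1 - \cos k_j(\theta - \phi_j)\big)
 + \tfrac{b_j}{2}\big(1 - \cos(\theta - \psi_j)\big),$$

a dominant `k_j`-fold term placing `k_j` wells plus a small single-period
tilt (`b < A`) that breaks their degeneracy, and consecutive dimensions are
coupled by weak terms `c (1 - cos(\theta_j - \theta_k - \varphi))/2`.
Amplitudes (`A` in 0.15–0.30 eV, tilts 0.02–0.05 eV, couplings ~0.03 eV)
are drawn once per seed and mimic torsional barrier heights. Two design
points matter:

* **Well multiplicities are capped at 3** (two- and three-fold,
  rotamer-like). Higher multiplicities space wells so closely (e.g. 72
  degrees for five-fold) that in moderate dimensions genuinely distinct
  minima fall under the 15-degree *mean*-distance similarity rule and
  collapse during deduplication — a degenerate benchmark. The per-dimension
  multiplicities are the product of 2s and 3s closest to `n_wells`.
* **Curvature is bounded away from zero** near every stationary point: an
  earlier localized-well construction left near-flat shelves between wells
  where the couplings carved fragile quasi-degenerate dips, which no
  smooth surrogate can be expected to reproduce stably.

The construction deterministically re-points and strengthens the tilt
until the global minimum is separated from the runner-up by at least
5 meV, and offsets all energies by about `-2e4` eV so the `E0`-shift
pathway is exercised with realistic raw magnitudes. `bruteforce_minima()`
— the oracle — scans the full periodic grid (default 24 points per
dimension), keeps points strictly below all axis neighbours, polishes each
with the analytic gradient to a `1e-6` eV/degree stationarity, and
deduplicates with the same 15-degree rule.

What the generator does **not** emulate: Cartesian relaxation that changes
bond lengths/angles, steric-clash-driven invalid samples (the bare surface
is defined everywhere; clash screening activates only when a molecule spec
is attached), reference-level energy noise, and multi-reference
pathologies. Tests passing on this surface therefore demonstrate the
machinery — sampling, modelling, extraction, bookkeeping — not chemical
accuracy on real peptides.

## The workflow

`run_lols()` iterates: alpha cutoff → VAE retraining on the included
records → encode pool → rectangle-sample `batch_size` candidates → decode,
evaluate, append. Every `k` iterations (and always at `M`) the GP is
fitted to the full pool and its merged minima are banked. Candidates from
*all* energy models are retained because GP refits fluctuate and minima
can transiently disappear; everything banked is refined at the end on the
true backend energy (conjugate gradients, at most 200 steps, converged at
gradient norm `0.01` eV/degree — the analog of the usual 0.01 eV/Å force
threshold), non-converged candidates are dropped and counted, and the
survivors are deduplicated and re-referenced to the new global minimum.
Initial data is seeded uniform sampling over the ranges — the one
intentional deviation from the published workflow, which seeds from a
Bayesian-optimization run; an externally produced pool in the data-pool
file format can be supplied instead (`initial_pool`).

In benchmark mode (known targets) the loop stops early when the
global-minimum target is achieved and at least 70% of all targets are
reached, judged on the banked (unrefined) candidates by the max-circular-
difference rule (< 15 degrees in every dimension). Three parallel seeded
runs are merged *after* refinement (the published account does not state
the order) by union plus deduplication.

The real-space baseline replaces latent sampling with uniform draws in
dihedral space, keeping every other stage identical. The published
baseline description says a model is fitted "every k samples" where the
main loop fits every `k` iterations; for budget parity this package fits
every `k * batch_size` samples, i.e. on the same schedule as the main
loop.

`map_latent_islands()` reproduces the latent-map analysis: the bounding
rectangle of the encoded data is discretized (`grid_n = 400` in production
analyses; tests use coarser grids), every grid point is decoded, assigned
to its nearest reference conformer when the mean circular difference is
below 30 degrees, and per-target island area fractions are reported for
targets within an energy window (default 0.5 eV).

## Problem sizes and numerical choices in the shipped suite

The suite's end-to-end check enumerates a seeded 5-D surface
(9 oracle minima at 24 grid points per dimension), then runs three seeded
searches with `initdata = 100`, `M = 10`, `batch_size = 30`, `k = 5`,
`beta = -1`, `layersize = 80`, and requires the merged, refined result to
contain the oracle global minimum and at least 70% of the window minima.
The surrogate-oracle equivalence check uses 500 training points on a 2-D
surface; the bias check trains `beta = 0` and `beta = -3` pairs on a fixed
400-record 5-D pool across three seeds and compares the mean scaled energy
of 500 decoded rectangle draws. These sizes were chosen so each property
is exercised at a scale where its failure modes (lost minima, merged
basins, biased sampling) would be visible.

## Known limitations

* The latent space is 2-D by default and known to become sparse as `D`
  grows; higher latent dimensions are configuration-plumbed but untested.
* Refinement for molecular backends delegates to the backend's own
  optimizer through the external-program stub; the package does not
  implement Cartesian geometry optimization.
* Latent-space surrogates and acquisition functions are deliberately
  absent: the latent space is neither smooth nor continuous enough to
  support them, which is why space-filling rectangle sampling is used.
* The alpha cutoff is the only outlier rule; no transition-state or
  reaction-path machinery is included.
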