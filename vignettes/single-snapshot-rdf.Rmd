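---
title: "Predicting time-averaged liquid structure from one configuration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting time-averaged liquid structure from one configuration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The radial distribution function g(r) is the workhorse descriptor of
short-range order in liquids: the probability, relative to an ideal gas at
the same density, of finding a particle at distance r from a reference
particle. Estimated from a *single* snapshot of a molecular dynamics (MD)
trajectory it is dominated by thermal noise; the quantity of interest is its
temporal average over a long equilibrium trajectory,

$$ g_\mathrm{ref}(r) \;=\; \frac{1}{N_t}\sum_{i=1}^{N_t} g_{t_i}(r), $$

which normally requires simulating that long trajectory in the first place.
`pointrdf` trains a surrogate that maps one configuration — an unordered set
of atoms with positions, velocities and species labels, plus the condition's
two thermodynamic state scalars — directly to $g_\mathrm{ref}(r)$ for every
species pair at once. A model trained across a grid of thermodynamic
conditions can then produce the equilibrium structure of an *unseen*
condition from a single frame, at a tiny fraction of the cost of the long
simulation.

## The model

Each snapshot is treated as a point cloud: an $N \times (3+M)$ matrix whose
rows are atoms and whose columns are positions, then (optionally)
velocities, then a one-hot species block. The network has three stages:

1. **Shared per-point layers.** A multilayer perceptron (ReLU activations)
   is applied to every row independently.
2. **Symmetric max pooling.** A per-feature maximum over the $N$ points
   produces one global feature vector. Because `max` is symmetric, the
   output is *exactly* invariant under any permutation of the atoms — a
   property the tests assert bitwise — and under duplication of points.
3. **Fused head.** The two state scalars (here: number density and
   temperature, standardized by training-set mean and deviation) are
   concatenated to the pooled feature, and a fully connected head (linear
   final layer) emits the concatenated per-pair g(r) vectors, one block of
   `n_bins` values per species pair in lexicographic pair order.

Training minimizes the mean squared error between the predicted vector and
the condition's full-trajectory averaged RDF, with the Adam optimizer at
learning rate 0.001 and early stopping on a held-out validation condition
(the best-validation parameters are restored). Splits are made at the level
of *conditions*, never frames, so no information about a test condition's
trajectory can leak into training.

### Architecture defaults

The shared stack is `16, 16, 32` wide and the head `32, 32`: a deliberately
compact network, chosen so that full training runs complete in minutes on a
single CPU core while retaining far more capacity than the
condition-to-curve map requires at this scale. A 2-4x wider stack was
profiled during development and converged to the same held-out error, only
slower. The classic point-cloud
architectures this design descends from use wider stacks (up to a 1024-wide
global feature); `model_spec()` exposes the widths, and nothing else in the
pipeline assumes the defaults. No learned alignment/transformer blocks are
used: the pipeline's inputs live in a fixed periodic box, so canonicalizing
rotations would discard physically meaningful orientation information —
and the fused stack of per-point layers, pooling and head is the entire
architecture.

Positions enter as fractional coordinates (divided by the box edge),
velocities divided by their training-set root mean square; both choices
bound the inputs and make unit systems interchangeable. Targets are
predicted on their natural g(r) scale with plain He initialization and zero
biases; initializing the output bias at the training-set mean curve was
tried and rejected — it parks the optimizer at a validation plateau an
order of magnitude above what the standard start reaches. Negative predicted g values are
clamped to zero only at the prediction interface, never inside the loss, so
training is not biased by the clamp.

### One-hot convention

Species labels are dense 0-based integers; label 0 maps to the *last*
one-hot column, so in a two-species system the first species encodes as
`[0, 1]` and the second as `[1, 0]`. The convention is arbitrary but fixed
and documented, and checkpoints store the column order.

## The data generator

The labelled-data source is a compact Lennard-Jones MD engine in reduced
units ($\sigma = \epsilon = m = k_B = 1$):

- truncated-and-shifted pair potential, cutoff $2.5\,\sigma$, forces the
  exact negative gradient of the shifted energy (tested against central
  finite differences);
- velocity-Verlet integration with a Berendsen-style velocity-rescaling
  thermostat (`coupling = 0` recovers NVE, where total-energy drift stays
  below $10^{-3}$ relative over 1000 steps at `dt = 0.002`);
- minimum-image convention in an orthorhombic periodic box; plain
  $O(N^2)$ pair loops, which at $N \le 1500$ beat cell-list bookkeeping;
- initial configurations on a perturbed cubic lattice with a guaranteed
  minimum separation of $0.85\,\sigma$, thermal velocities with the
  aggregate momentum removed and the kinetic temperature rescaled exactly
  to target.

The engine runs constant-volume (NVT) production and treats **number
density** as the condition's second state variable; the mean virial
pressure over production is recorded so every condition still carries a
pressure label. A barostat would add complexity without changing the
surrogate's contract — the network consumes two state scalars either way —
and a fixed box keeps the radial grid constant within a trajectory.

Two systems exercise every code path: a single-species liquid (one RDF) and
an equimolar binary mixture with Lorentz–Berthelot cross terms
($\epsilon_2 = 0.7$, $\sigma_2 = 0.88$, $m_2 = 0.8$; mildly asymmetric so
the three partial RDFs differ).

### What the generator emulates — and what it does not

It reproduces the *structure* of the problem: liquids whose equilibrium RDF
varies smoothly with temperature and density, multiple species, a noisy
single-snapshot estimate versus a converged temporal average. It does not
emulate real force fields (no electrostatics, bonds or constraints), NPT
ensembles, or production-scale statistics. Passing tests therefore
demonstrate the method's machinery and its desk-scale behaviour, not
accuracy on any particular real liquid.

## The desk-scale experiment

`run_rdf_experiment()` is the whole pipeline under one seed:

- 12 conditions: $T \in \{0.85, 0.95, 1.10, 1.25\}$ ×
  $\rho \in \{0.70, 0.75, 0.80\}$, inside the Lennard-Jones liquid/dense
  fluid region;
- 400 atoms per condition; 1200 equilibration + 1500 production steps at
  `dt = 0.005`, sampled every 10 steps → 150 frames per condition;
- radial grid: 100 bins up to $\min(4\sigma, L/2)$;
- inputs from the first 20% of each trajectory (the "short run" the
  surrogate sees), labels from the full run — the temporal-average
  definition above;
- condition split 10/1/1 (the 80/10/10 rule at $n = 12$), Adam at
  lr 0.001, batch size 8, up to 2000 epochs with early-stopping patience
  300 (validation-MSE improvements genuinely continue for roughly a
  thousand epochs at this learning rate, so a short patience would stop at
  an unconverged plateau).

These sizes were chosen once as the smallest grid that keeps a non-trivial
held-out interpolation task (the test condition is an unseen interior or
edge point of the $(T, \rho)$ grid) while a full run stays in the
minutes-not-hours range on one CPU core. Evaluation reports, per held-out
frame, the coefficient of determination $R^2$ against the ground truth, the
per-bin mean squared error $\varepsilon$, and the L1 relative error — for
the model *and* for the direct-MD single-snapshot baseline on the same
frames, whose ratio is the headline "how many orders of magnitude better
than one raw snapshot" number.

## Numerical choices and edge cases

- **RDF binning.** Half-open bins $[k\Delta r, (k+1)\Delta r)$; a distance
  exactly at `r_max` is discarded; exact spherical-shell volumes; ordered
  pair counting with $N_b - 1$ partners for same-species pairs, which makes
  the ideal-gas expectation exactly 1. The estimator is verified bin-for-bin
  against a brute-force double loop.
- **Error metric.** $\varepsilon$ is the per-bin mean squared deviation —
  the same quantity the training loss minimizes. The L1 ratio
  $\sum_k |g_p - g_r| / \sum_k |g_r|$ is reported as the relative error.
  $R^2$ is taken about the reference-curve mean and is undefined (an error,
  not a silent value) for a constant reference.
- **Degenerate inputs.** Snapshots need $N \ge 2$; a species pair absent
  from a snapshot, a grid wider than the half-box, mixed grids in one
  average, and non-orthorhombic boxes in the readers all fail loudly rather
  than coerce.
- **Ties in max pooling** resolve to the first point in storage order; the
  choice only affects gradient routing, not the pooled value.
- **Early stopping** monitors the validation MSE each epoch; training stops
  `patience` epochs after the last improvement and restores the best
  parameters, so the reported model is never a late-epoch overfit.
- **Determinism.** Every stochastic step (lattice shuffle, velocities,
  species assignment, split, initialization, epoch shuffles) draws from a
  seed that is set explicitly; per-condition engine seeds are derived from
  one master seed. Identical seeds give bitwise-identical trajectories,
  splits and fits on one platform.
- **Archive format.** The dataset container is a versioned RDS file behind
  `save_archive()`/`load_archive()`; text interchange uses the LAMMPS dump
  and extended XYZ dialects described in their readers.

## Known limitations

- The engine is NVT-only with short-range pair forces; conditions are
  (T, density) points, and pressure is measured, not imposed.
- One fixed species set per trained model: a snapshot containing a species
  the normalizer never saw is rejected, by design.
- The surrogate interpolates between training conditions; nothing
  constrains it outside the training grid's hull, and corner conditions in
  the split are measurably harder than interior ones.
- Single-CPU training bounds the practical dataset size; the widths above
  are matched to that budget, not to production-scale data.
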