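---
title: "Simultaneous rigid-body fitting of assembly components into cryo-EM maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous rigid-body fitting of assembly components into cryo-EM maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gafem)
```

## The problem

A low- to intermediate-resolution 3D electron-microscopy map of a
macromolecular assembly shows the overall envelope of the complex, but not
where each protein component sits or how it is oriented. Given atomic
structures of the individual components, *assembly fitting* asks for the
rigid-body placement of all components simultaneously so that their combined
simulated density matches the map while the components do not overlap. The
search space is astronomical: with a 10° angular step, three components
already admit `(360/10)^9 ≈ 1e14` purely rotational configurations
(`rotational_configurations(3)`), so exhaustive search is hopeless and a
stochastic global optimizer is used instead.

## The model and its fitness function

A candidate assembly is encoded as a **genotype** with two genes per
component: a translation gene (a 3-vector in Å giving the displacement of the
component centroid from the map centre) and a rotation gene (an integer index
into a library of 5,000 approximately uniform rotations, sampled as
normalized 4D Gaussians on the quaternion 3-sphere). Rotations act about the
component centroid, which decouples the two genes: crossover can exchange a
position without dragging an orientation change along.

The fitness of a decoded model with $n$ components is

$$F = n \cdot \mathrm{MI} - \mathrm{PS}$$

* **MI** is the mutual information between the binned densities of the
  *probe* map (the model blurred onto the target grid) and the *target* map:
  each map's densities are split into 20 equal-width bins spanning its own
  range, and
  $\mathrm{MI} = \sum_{x,y} p(x,y)\,\log\frac{p(x,y)}{p(x)\,p(y)}$
  over all aligned voxels, in natural-log units. MI is invariant to any
  monotone rescaling of either map's density scale and equals the binned
  entropy of the target when probe and target coincide, which makes it a
  robust goodness-of-fit score across maps with different density
  conventions.
* **PS** penalizes clashes: each component occupies the set of 3.5 Å voxels
  (on one shared, origin-snapped lattice) containing its backbone or Cβ
  atoms, and PS sums, over component pairs, the overlap fraction
  $|occ_i \cap occ_j| / (|occ_i| + |occ_j|)$. Two identical superposed
  components score exactly 0.5 per pair, so severe interpenetration is
  heavily penalized while grazing contacts cost little.

Probe maps are simulated by blurring every atom with an isotropic Gaussian of
$\sigma = 0.356 \times \text{resolution}$, truncated at $3\sigma$ (which
keeps 97.1% of each atom's mass and is accounted for in the tests'
tolerances), with identical unit amplitude for all heavy atoms. The probe is
always simulated at the target's nominal resolution on the target's exact
grid, the only choice under which the generating model maximizes MI against
its own simulated map.

## Sampling

The genetic algorithm (one *run*) evolves a population of 160 genotypes for
100 generations (defaults of `ga_config()`):

* **Seeding.** Feature points are extracted from the map by neural-gas
  vector quantization (`vector_quantize()`): voxels above a
  mean + 2σ density threshold are sampled proportionally to density, and
  `k` codebook vectors (k = number of components) are annealed with the
  rank-based neural-gas update, learning rate 0.1 → 0.001 and neighbourhood
  range k/2 → 0.01 over 10,000·k samples (exponential schedules). Half the
  initial population places each component exactly on a random feature
  point; the other half adds a random displacement of length up to twice
  the minimum feature-point separation. Orientations are drawn uniformly
  from the rotation library.
* **Crossover (90% of children).** Two parents are chosen by size-2
  tournaments; the child copies the fitter parent and, per gene, swaps in
  the other parent's value with probability 0.8; swapped genes are then
  mutated with a rate that decays linearly from 0.2 (generation 1) to 0.01
  (last generation). Translation mutations add a random vector of length up
  to the minimum feature-point separation; rotation mutations redraw the
  library index uniformly.
* **Diversity (10% of children).** The fittest genotype has the gene pairs
  of two random components swapped, then every gene mutated at a constant
  rate 0.1 — the operator that can repair permuted component assignments in
  one move.
* **Selection.** Children and parents merge (320 genotypes) and the best
  160 survive; ties favour parents, then creation order, making runs fully
  deterministic given their seed. The merge is elitist, so the
  best-fitness trace recorded in `run_ga()`'s `ConvergenceTrace` is
  non-decreasing by construction.

Because single runs are stochastic and can converge to local optima, an
**ensemble** of 20 independent runs (`run_ensemble()`) is ranked by fitness;
rank 1 is the highest-scoring (HS) assembly, and when a reference structure
is available the best-predicted (BP, lowest RMSD) model and its rank are
reported too.

## Assessment metrics

* **Topology score (TS)** — the fraction of components whose predicted
  centre of mass falls within (inclusively; fixed for determinism) a sphere
  around the native centre of mass with radius the native radius of
  gyration. Centres of mass are unweighted means over atoms: the score is
  geometric, and the same convention is used for seeding and placement, so
  no mass table is needed.
* **CPS / APS** — per component, the translation (Å, centre-of-mass
  displacement) and rotation (degrees, angle of the optimal Kabsch rotation
  between centred Cα sets) needed to superpose prediction onto native; APS
  averages both over components.
* **RMSD** — the mean over components of per-component Cα RMSD computed in
  the common map frame *without* re-superposition (the components are rigid,
  so superposing would erase exactly the placement error being measured).
  For assemblies with identical components (detected by identical Cα residue
  sequences, or supplied explicitly) the predicted-to-native correspondence
  is chosen by exhaustive enumeration within each identical group (supported
  to size 8) to minimize the average; TS and CPS are then computed under
  that correspondence.

## Synthetic fixtures: what they emulate, and what they do not

`make_assembly()` builds assemblies with known ground truth so the whole
pipeline is testable without downloads: compact self-avoiding pseudo-Cα
chains (3.8 Å steps, non-consecutive contacts ≥ 4 Å, centroid-biased walk)
with idealized backbone and Cβ atoms and seeded random sequences, packed
with centroid separations ≥ 25 Å and native clash penalty < 0.05, then
blurred into a target map (default 10 Å resolution, 3.5 Å voxels, 10 Å
margin). Component sizes are spread evenly across the requested range
(default 30–70 residues) because heterogeneous component sizes — typical of
real assemblies — are what make the component-to-density-blob assignment
identifiable by the fitness function.

The fixtures emulate the *geometry* of the problem (distinct globular rigid
bodies in a shared envelope at realistic packing) but not real protein fold
statistics, sidechain chemistry, map noise, or resolution anisotropy.
Passing the recovery tests therefore demonstrates that the sampler and
scores behave as designed on well-posed instances; performance on
experimental maps additionally depends on feature-point quality, which the
Hausdorff-distance diagnostics (`hausdorff()` between VQ points and native
centroids) quantify.

## Numerical choices and scaled-down test conditions

* Natural logarithm for MI; per-map equal-width binning over each map's own
  full range, all voxels included; a constant map collapses to one bin and
  carries zero information.
* Gaussian truncation at 3σ (< 1.2% mass loss) with unit atom amplitudes.
* The clash lattice origin is snapped to a multiple of the voxel size so
  pairwise intersections use identical voxel addressing; the penalty is
  invariant to global rigid motion up to voxel-discretization jitter, which
  vanishes as the lattice is refined.
* Quaternion libraries, VQ runs, GA runs and fixtures are all
  seed-deterministic; ensembles derive per-run seeds from the master seed.
* Desk-scale experiments in the test suite use a 3-component fixture at
  10 Å with centroid-quality seeds and 5-run ensembles of population 40
  over 30 generations — small enough to run in minutes, large enough that
  the ensemble's highest-scoring model recovers the native topology. At
  this reduced scale individual runs occasionally settle into a permuted
  component assignment whose rotations have co-adapted (a genuine local
  optimum, clearly separated in fitness from correct solutions); the
  ensemble ranking resolves this, which is precisely why the method runs
  independent GAs and ranks them.

## Known limitations

Rigid components only (no flexibility, no partial assemblies); rotational
placement at low resolution is much less determined than translational
placement, so recovered orientations can deviate substantially even when the
topology is correct; no symmetry restraints; feature-point quality bounds
achievable accuracy when components are elongated or tightly packed; no
refinement stage is included — ranked models are emitted unrefined and can
be passed to any external real-space refinement tool.

## A worked session

```{r example, eval = FALSE}
fx <- make_assembly(fixture_spec(n_components = 3, resolution = 10, seed = 42))
pts <- vector_quantize(fx$map, neural_gas_params(3, seed = 1))
hausdorff(pts, fx$centroids)       # feature-point quality vs ground truth

cfg <- ga_config(population_size = 40, generations = 30, n_runs = 5, seed = 1)
ens <- run_ensemble(fx$map, fx$components, pts, cfg, reference = fx$components)
ens                                 # ranked fitness, BP rank
assess_assembly(ens$results[[1]]$model, fx$components)
```
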