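# gafem

Simultaneous rigid-body fitting of multiple atomic components into a low- to
intermediate-resolution 3D-EM density map of their assembly, for structural
biologists interpreting cryo-EM or subtomogram-averaged maps of complexes
whose component structures are known individually.

## Method

A candidate assembly is a **genotype**: per component, a translation gene
(displacement of the component centroid from the map centre, Å) and a
rotation gene (an index into a library of 5,000 uniform quaternions). An
elitist genetic algorithm evolves a population of 160 genotypes for 100
generations — tournament selection (size 2), per-gene crossover at
probability 0.8 with a linearly decaying mutation rate (0.2 → 0.01), a
diversity operator that swaps component gene pairs in the fittest genotype
(10% of children, constant mutation rate 0.1), and merge selection keeping
the best 160 of 320. The fitness of an *n*-component model is

    F = n × MI − PS

where MI is the mutual information between the 20-bin density distributions
of the target map and a probe map simulated from the model (Gaussian
point-spread, σ = 0.356 × resolution), and PS is a clash penalty summing,
over component pairs, the overlap fraction of their backbone/Cβ occupancy
grids on a 3.5 Å lattice. Populations are seeded on feature points extracted
from the map by neural-gas vector quantization at a 2σ density threshold;
20 independent runs are ranked by fitness. Predictions are assessed against
a reference by topology score (TS), component/assembly placement scores
(CPS/APS), and permutation-aware Cα RMSD; feature-point quality is measured
by the Hausdorff distance to native centroids.

## Worked example

A synthetic 3-component assembly with a 10 Å simulated map, fitted with a
reduced configuration (5 runs, population 40, 30 generations):

```r
library(gafem)
fx  <- make_assembly(fixture_spec(n_components = 3, resolution = 10, seed = 42))
pts <- vector_quantize(fx$map, neural_gas_params(3, seed = 1))
hausdorff(pts, fx$centroids)
#> [1] 0.8850108
cfg <- ga_config(population_size = 40, generations = 30, n_runs = 5, seed = 1)
ens <- run_ensemble(fx$map, fx$components, pts, cfg, reference = fx$components)
ens
#> <GA ensemble: 5 runs>
#>   rank  1: F =   1.2116 (MI = 0.4039, PS = 0.0000), RMSD = 15.22 A
#>   rank  2: F =   1.1867 (MI = 0.3981, PS = 0.0078), RMSD = 7.77 A
#>   rank  3: F =   1.1395 (MI = 0.3798, PS = 0.0000), RMSD = 11.62 A
#>   rank  4: F =   1.0999 (MI = 0.3666, PS = 0.0000), RMSD = 16.21 A
#>   rank  5: F =   1.0811 (MI = 0.3604, PS = 0.0000), RMSD = 25.87 A
#>   best-predicted model at rank 2
assess_assembly(ens$results[[1]]$model, fx$components)
#> <Assessment: TS = 1.00, APS = (0.68 A, 164.8 deg), RMSD = 15.22 A>
```

The vector-quantization points land within 0.9 Å (Hausdorff) of the true
component centroids; the highest-scoring model recovers the native topology
(TS = 1: every component centroid inside its native radius-of-gyration
sphere, here to within 0.9 Å), while the large APS rotation reflects that
component *orientations* are weakly determined at 10 Å resolution. The
native configuration itself scores F = 2.46 — above every prediction, as
expected.

The same pipeline is scriptable from a shell via the installed `gafem`
entry point (`fit`, `score`, `assess`, `vq`, `simulate-map`, `make-fixture`
subcommands), which writes ranked model PDBs, a `scores.tsv`, per-run
convergence traces and a JSON manifest of seeds and configuration.

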