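# follisim

Multiscale simulation and analysis of CXCL13 chemokine gradients in B-cell
follicles.

CXCL13, secreted by follicular reticular cells (CD21/35⁺ follicular dendritic
cells and CD21/35⁻ reticular cells), guides CXCR5⁺ B cells within the lymph
node follicle. Whether the chemokine acts as a freely diffusing, homogeneous
field or as extracellular-matrix-immobilized, short-range gradients changes
what B cells can "read" while scanning the stromal network for antigen.
`follisim` implements a complete in silico platform to study this question,
together with the statistical analyses used to confront it with imaging data:

* **Reticular network synthesis and topology.** A geometric generator builds
  3D follicular networks (dense FDC core, RC shell and subcapsular rim,
  distance-decaying connections, rare long-range shortcuts) calibrated so
  that their topology matches measured follicle networks: ~198 nodes, ~1163
  edges, mean local clustering coefficient C_local ≈ 0.60, transitivity
  C_global ≈ 0.57 and mean shortest path length L ≈ 4.17 — far more clustered
  than, yet nearly as short-ranged as, an equivalent Erdős–Rényi G(n, m)
  graph (C_local ≈ 0.06, L ≈ 2.41), the small-world signature quantified by
  the σ and ω indices.
* **Chemokine fields.** A discretized reaction–diffusion model (secretion at
  stromal nodes, diffusion, decay, optional reversible ECM immobilization)
  with an explicit FTCS stepper and a sparse direct steady-state solver.
  Model 1 (immobilized: D = 0.19 µm² s⁻¹, screening length ≈ 15 µm) and
  model 2 (soluble: D = 1.6 µm² s⁻¹, near-homogeneous) are parameterized at
  equal total chemokine mass.
* **B-cell agents.** CXCR5 receptor kinetics (binding, unbinding,
  internalization, recycling) coupled to a biased persistent random walk:
  orientation = normalize(persistence · previous + random unit vector +
  chemotactic bias), where the bias is the receptor-occupancy difference a
  cell can resolve across its own body — saturated or desensitized receptors
  make shallow or uniform fields illegible. Emergent statistics: cell speed,
  meandering index, motility coefficient and stromal-network scanning rate.
* **Emulation and optimization.** Latin hypercube designs over the 13
  simulation parameters, per-output feed-forward neural surrogates
  (13 inputs → three sigmoidal hidden layers → 1 output), and NSGA-II
  multiobjective search (minimize deviation from experimental speed,
  meandering and motility targets; maximize scanning rate) with Pareto-front
  extraction, hypervolume, parameter marginals and the Vargha–Delaney A-test.
* **Spatial statistics and single-molecule tracks.** Moran's I correlograms
  with permutation testing and the decorrelation distance D_uncorrelated for
  intensity images or simulated fields; per-track diffusion coefficients
  from short-lag MSD fits (513 Hz framing, 40 nm localization noise) with
  immobile/mobile fraction decomposition.

## Worked example

```r
library(follisim)

# 1. synthesize a calibrated follicular network and inspect its topology
net <- synthesize_follicle_network(seed = 1)
topology_report(net)
#> Network topology report
#>   nodes: 198  edges: 1293  (largest component: 100.0%)
#>   mean degree: 13.06  mean edge length: 28.09 um
#>   C_local: 0.590  C_global: 0.584  L: 3.837 hops

# 2. build the two competing chemokine fields at equal total mass
cmp <- run_model_comparison(experiment_config(seed = 1, replicates = 20))
cmp
#> Model comparison (immobilized vs soluble gradients)
#>   scanning rate median: model 1 = 6.850, model 2 = 2.700 nodes/cell/h
#>   Vargha-Delaney A = 1.000 (large effect)
```

The scanning rate is the number of distinct stromal cells a B cell contacts
per hour. Immobilized, short-range gradients (model 1) guide cells onto the
node-dense network and more than double the scanning rate of the same cells
under a homogeneous soluble field (model 2); A = 1.0 means every model-1
replicate out-scanned every model-2 replicate (A ≥ 0.71 is a large effect).

Single-molecule mobility, as in the imaging experiments:

```r
tracks <- simulate_tracks(D = 0.19, n_tracks = 500, n_frames = 12, seed = 2)
D_hat <- track_diffusion_table(tracks)$D
mobility_fractions(list(untreated = D_hat))
```

## Command line

A thin CLI over the package functions lives at `inst/cli/follisim.R`:

```sh
Rscript inst/cli/follisim.R topology --in net.graphml --nulls 100 --seed 7 --out report.json
Rscript inst/cli/follisim.R synth --seed 3 --out follicle.graphml
Rscript inst/cli/follisim.R compare-models --config experiment.yaml
```
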