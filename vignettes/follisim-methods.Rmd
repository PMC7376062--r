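---
title: "Models and methods behind follisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind follisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`follisim` is a multiscale platform for studying how the architecture of the
CXCL13⁺ follicular reticular cell network shapes chemokine gradients and, in
turn, B-cell scanning behavior. This vignette documents the models, their
assumptions, the tunable parameters with their defaults and units, the
numerical choices, and what the shipped synthetic data do and do not
emulate. Every empirical number quoted here is computed by the package's own
test suite or by `scripts/acceptance.R`.

## 1. Reticular networks and their topology

A network is an undirected spatial graph: nodes are CXCL13-producing stromal
cells, labelled `FDC` (CD21/35⁺ follicular dendritic cells) or `CD21neg_RC`
(CD21/35⁻ reticular cells, including the marginal reticular cells of the
subcapsular rim), with 3D positions in micrometres; edges are physical
connections between neighboring cells.

`topology_report()` computes node/edge counts, degree and Euclidean
edge-length tables, the mean local clustering coefficient (`C_local`),
transitivity (`C_global`) and the mean shortest path length `L` in hops.
Conventions, chosen where the quantities admit more than one reading:

* Local clustering of degree-0/1 nodes is defined as 0 and included in the
  mean (the alternative — dropping such nodes — inflates sparse graphs).
* `L` averages over unordered reachable pairs. By default it is computed on
  the largest connected component and the component's coverage fraction is
  reported; `paths = "reachable"` instead averages all reachable pairs of
  the full graph. For undirected graphs ordered and unordered averaging
  coincide, so only the treatment of unreachable pairs differs between the
  exposed options.

The random reference is the Erdős–Rényi `G(n, m)` model — a fixed *edge
count*, not a fixed edge probability — because the comparison of interest is
against "an equivalent random network with the same number of nodes and
edges". At the measured follicle size (198 nodes, 1163 edges) these nulls
give mean `C_local` ≈ 0.06 and mean `L` ≈ 2.41.

`small_world_indices()` computes σ = (C/C_rand)/(L/L_rand) and
ω = L_rand/L − C/C_latt, with C the mean local clustering coefficient,
C_rand/L_rand averaged over `n_null` G(n, m) draws (disconnected nulls are
redrawn and counted), and C_latt the clustering of a ring lattice whose even
degree is the network's mean degree rounded down — the lattice construction
is a convention, stated here because σ and ω are only defined up to the
choice of references.

## 2. Synthetic follicular networks

`synthesize_follicle_network()` is a geometric generator, not a
reconstruction of any particular imaged follicle. It emulates the follicle's
gross anatomy inside an imaging-style slab (default 500 × 500 × 35 µm,
mirroring the aspect of confocal stacks): FDCs uniform in a central core
disc (fraction `fdc_core_fraction` = 0.62 of the follicle radius, default
radius 140 µm), RCs in the surrounding shell with a `cap_fraction` = 0.3
placed on a subcapsular rim band (`rc_shell_thickness` = 25 µm, upper arc).
Pairs within `connect_radius` = 39 µm connect with probability
exp(−d / `connect_decay`), `connect_decay` = 800 µm, and a
`shortcut_fraction` = 0.005 of extra edges joins random non-adjacent pairs
(flagged per edge). A run whose largest component covers less than half the
nodes fails loudly rather than returning a fragmented graph.

The defaults above are the output of the shipped calibration
(`calibrate_generator()`: random search plus shrinking local refinement over
the four geometric parameters, ≥ 20 generator seeds per candidate, weighted
squared relative error on edge count, C_local, C_global and L). Calibrated
against the measured follicle statistics (198 nodes, 1163 edges,
C_local 0.60, C_global 0.57, L 4.17), the generator achieves means of about
1196 edges, C_local 0.606, C_global 0.597 and L 4.14 over 40 seeds. The
FDC:RC split (89:109) is a parameter, not a measurement — the source data do
not report per-subtype counts.

What the generator does *not* emulate: per-follicle anatomical variability
beyond sampling noise (node counts are fixed per parameter set), dendrite
morphology, and any correlation between subtype and connection range beyond
what geometry induces. Tests passing on generated networks therefore
demonstrate that the *statistics* pipeline is correct and that the generator
hits its calibration contract — not that any individual generated network is
anatomically faithful.

## 3. Chemokine reaction–diffusion model

Fields live on a regular voxel lattice (default spacing 10 µm for
simulation work, 5 µm where fine gradients matter; stored as amount per
voxel). The soluble pool obeys

∂c/∂t = D∇²c + s − λc − k_on·c + k_off·i,

and the immobilized pool (active only with `ecm_pool = TRUE`) obeys
∂i/∂t = k_on·c − k_off·i − λ_i·i. Immobilized chemokine does not diffuse —
that is what "immobilized" means here — and decays at λ_i = λ by default
(overridable). Secretion is deposited at each stromal node's nearest voxel
with subtype-specific rates.

Numerics:

* `field_step()` is forward-time central-space (FTCS), chosen for
  transparency; it refuses any `dt` violating the positivity bound
  dt ≤ 1/(6D/h² + λ + k_on) and suggests a valid one. Reflective (zero-flux)
  boundaries are the default — the follicle is treated as a closed domain —
  with an absorbing option modeling sinks at the follicle edge. Mass is
  conserved to machine precision under pure diffusion.
* `run_to_steady_state()` exploits the model's linearity: the default
  "direct" method assembles the sparse steady-state operator and solves it
  by supernodal Cholesky factorization, which is exact and orders of
  magnitude faster than time-stepping at small decay rates; the "iterate"
  method (used by the tests that exercise the dynamics) steps the explicit
  scheme until the maximum relative change per simulated second falls below
  `tol`.
* Against the screened point-source solution c(r) ∝ e^(−r/ℓ)/r with
  ℓ = √(D/λ), shell-averaged steady fields agree to well within 5% for
  r between 3 and 8 voxel spacings.

The two competing gradient hypotheses are fixed parameterizations
(`model_parameterization()`): model 1 (immobilized) takes D = 0.19 µm² s⁻¹ —
the measured single-molecule median in untreated tissue — with λ chosen so
that the screening length is ≈ 15 µm, giving short sharp gradients proximal
to secreting cells; model 2 (soluble) takes D = 1.6 µm² s⁻¹ (the
heparinase-treated median) with λ = 10⁻⁵ s⁻¹ (≈ 19 h half-life), giving a
near-homogeneous field. The λ values are module defaults chosen to realize
the two regimes, not measured quantities. Secretion is rescaled so both
steady states carry the same total mass (default 2000 units), holding
overall concentration fixed; with the default geometry model 1 keeps ≈ 99%
of its chemokine within 50 µm of the secreting cells, model 2 ≈ 41%. The
explicit two-pool ECM model is off by default for model comparisons —
immobilization is emulated by low D and high λ, matching how the parameter
distributions were originally explored — and can be switched on to study
binding kinetics explicitly.

## 4. B-cell agents

Each agent carries a three-pool CXCR5 state (free, bound, internalized;
conserved total `R_total` = 10⁴): binding at k_on·c (k_on = 100 µm³ s⁻¹ with
concentration in µm⁻³, i.e. a dissociation constant of 5 × 10⁻⁴ µm⁻³ ≈ 1 nM),
unbinding k_off = 0.05 s⁻¹, internalization k_i = 0.01 s⁻¹, recycling
k_re = 0.001 s⁻¹. The exported `receptor_step()` is the plain explicit-Euler
integrator with a step-size guard; inside `run_simulation()` the fast
binding pair instead relaxes by an exact exponential update (with Euler for
the slow rates), which is unconditionally stable and lets the motility time
step (dt = 5 s) be used at any concentration. The two integrators agree as
dt → 0.

Motility is a biased persistent random walk:

orientation ← normalize(persistence · previous + random unit vector +
chemotactic bias),

with speed per step drawn Gamma(shape 4) around `v_mean` and reflective
collisions with the domain boundary. Three sensing choices matter and are
deliberate:

* The gradient is read as the concentration *difference across the cell
  body* (trilinear interpolation one cell radius either side of the center;
  `cell_diameter` = 10 µm). Raw voxel central differences alternate sign
  around discrete field maxima and pin cells by lattice artifact.
* The default transduction (`sensing = "occupancy_difference"`) converts
  that concentration difference into the equilibrium *receptor-occupancy*
  difference across the cell, K/(c+K)² · |∇c| · diameter with
  K = k_off/k_on, weighted by the cell's current surface-receptor fraction
  (free + bound, excluding internalized receptors). This is the quantity a
  cell can physically measure: saturated cells (c ≫ K) and desensitized
  cells (internalized receptors) are gradient-blind, so an equally massive
  but uniform chemokine field carries almost no directional information,
  while structured fields present a sensitive shell of c ≈ K around each
  source. Differences below `occ_detect` = 0.005 (half a percent of the
  receptor pool, a receptor-counting noise floor) are undetectable and the
  walk falls back to an unbiased persistent random walk.
* An alternative transduction (`sensing = "occupancy_scaled"`) scales the
  unit gradient direction by the bound fraction R_bound/R_total, with a
  relative-gradient detectability floor (`grad_detect` = 0.01 across the
  cell). It is simpler but discards the saturation-slope physics; it is kept
  as an option and exercised by the tests.

A stromal contact is logged the first time a cell center comes within
`contact_radius` = 6 µm of a node (cell radius ~5 µm plus a touching
margin); the scanning rate is unique contacts per cell per hour. Cells are
seeded uniformly within the follicle's radial extent — B cells under study
reside in the follicle. Cell–cell volume exclusion is omitted (dilute-agent
assumption); ligand consumption by internalization is available behind a
flag and off by default.

The motility defaults (chi = 8, persistence = 6, v_mean = 6.5 µm min⁻¹)
were calibrated once so that a model-1 simulation reproduces realistic
follicular B-cell migration — speed ≈ 6 µm min⁻¹, meandering index ≈ 0.4,
motility coefficient ≈ 20 µm² min⁻¹ — mirroring the original pipeline, which
calibrated its simulator against experimental two-photon migration
statistics before comparing gradient models. Those three target values are
placeholders for the unpublished experimental calibration set and should be
replaced by study-specific measurements for faithful reproduction
(`experiment_config(targets = ...)`).

With everything above in place the central emergent result follows: on the
same network at equal total chemokine mass, model-1 (immobilized) scanning
rates stochastically dominate model-2 rates with a Vargha–Delaney A ≈ 0.99
at 50 replicates per model — guidance onto the node-dense network roughly
doubles unique stromal contacts, while cells in the uniform field are nearly gradient-blind.

## 5. Migration summaries

`summarize_tracks()` resamples tracks to `dt_sample` (default 30 s, a
typical two-photon cadence) and reports per-run medians over cells: mean
step speed; meandering index (net displacement / path length); motility
coefficient as the ordinary-least-squares-through-origin slope of the
time-averaged MSD over the first quarter of lags divided by 2·dim (dim = 3);
and the scanning rate. Coarser resampling can only shorten measured paths,
so speed is monotone nonincreasing in `dt_sample` (asserted). Under an
unbiased persistent random walk the measured motility coefficient matches
the Fürth prediction ⟨v²⟩τ_p/3 within 15%, with τ_p derived from the mean
turn cosine of the orientation update by quadrature.

## 6. Emulation

`latin_hypercube()` (via the `lhs` package) stratifies each of the 13
parameters one-sample-per-bin. The 13 emulated inputs are a documented
contract: the five field parameters (D, λ, two secretion rates, k_on_ecm),
the five receptor constants and the three motility parameters. The prior
box (`default_param_ranges()`) brackets the competing hypotheses: D spans
0.05–2 µm² s⁻¹ (covering both measured medians), λ spans 10⁻⁵–10⁻³ s⁻¹
(half-lives ~19 h down to ~12 min — faster extracellular decay is not
plausible for a chemokine). Because the front's parameter marginals are read
against the box midpoint, the box is part of the study design; it was fixed
before the optimization experiments and is recorded here.

`train_emulator()` fits one feed-forward network per output statistic —
13 inputs, three sigmoidal hidden layers (default 24-16-8), linear output —
by full-batch Adam on min-max-normalized inputs and outputs, with a
75/15/10 train/test/validation split and optional k-fold cross-validated
selection of hidden sizes. Median (not mean) replicate responses summarize
each parameter set. Desk-scale defaults use 150 design points with 20
replicates each (the test suite runs a 120 × 6 campaign to stay within its
time budget); the full-scale profile (3000 × 100) is available via
`experiment_config(profile = "full")` and needs cluster time. On 50
held-out parameter sets the emulators rank-correlate with 20-replicate
simulator medians above 0.8 for every output (the test suite asserts this);
speed is the easiest output, the scanning rate — the most
interaction-driven — the hardest, and both improve with design size.

## 7. Multiobjective optimization

`nsga2()` is a from-scratch NSGA-II: fast nondominated sorting, crowding
distance, binary tournament, simulated binary crossover (η_c = 15) and
polynomial mutation (η_m = 20, rate 1/13) — the operators are conventions
(the algorithm choice names no operators), with population 100 and 250
generations as full-scale defaults (60 × 80 at desk scale). Maximization is
handled by an internal sign flip; reported objectives keep natural sense.
The four objectives: squared-error fit of emulated speed, meandering and
motility to the experimental targets (minimized) and emulated scanning rate
(maximized). The hypervolume is exact in 2D and seeded Monte Carlo above;
on the analytic bi-objective front f₂ = 1 − √f₁ the optimizer reaches the
true hypervolume within 1%.

`conflict_analysis()` reports Spearman correlations over front members
between the minimization-form scanning objective (its negative) and each fit
objective plus an aggregate-fit rank; negative correlation means conflict —
pushing scanning up pulls the migration statistics away from their targets.
At desk scale the aggregate conflict is ρ ≈ −0.8, and the front's diffusion
marginal sits well below the box midpoint while the decay marginal sits
above it: the optimizer rediscovers the immobilized-gradient regime.

## 8. Spatial autocorrelation

`bin_image()` averages intensities over square bins of 14.44 µm² (3.8 µm
side) by default, rounding the bin side to whole pixels and dropping partial
edge bins. `morans_correlogram()` uses binary distance-class weights (class
width = one bin side by default, classes up to half the grid diagonal; class
edges carry a small numerical tolerance so lattice distances are not split
by floating-point noise), two-sided permutation p-values with the (b+1)/(B+1)
estimator, and no multiplicity correction by default — D_uncorrelated is
defined as the center of the *first* class whose p-value exceeds α = 0.05,
so a per-class test mirrors that definition; a corrected variant
(`p_adjust`) is exposed. When every analyzed class stays significant,
D_uncorrelated is censored at the largest analyzed distance and flagged.
On equal-mass fields, the immobilized model decorrelates at much shorter
distances than the soluble model, as the correlogram comparison test
asserts. Checked against first principles: a checkerboard's
nearest-neighbor class gives I = −1 exactly, shuffled fields center on
E[I] = −1/(N−1), and p-values are uniform under the null.

## 9. Single-molecule track analysis

Tracks (513 Hz default frame rate, i.e. 1.949 ms intervals) shorter than
five consecutive frames are rejected at ingest. The per-track diffusion
coefficient is the slope of an unweighted linear fit to the time-averaged
MSD at lags 1–4 frames divided by 4 (2D motion) — the stated "linear fit to
the first four positions" is interpreted as this standard short-lag MSD
estimator, since a literal fit to four coordinates does not estimate a
diffusion coefficient; this interpretation is flagged here deliberately.
Localization noise (σ = 40 nm default) adds a constant 4σ² to every MSD
point, which the fit's intercept absorbs; `correct_noise = TRUE` also
subtracts the analytic floor before fitting (off by default, mirroring raw
published estimates — whether the originals corrected is unknown, so both
modes exist). Negative slopes floor at zero with a flag; log-log MSD slopes
above 1.5 flag directed (super-diffusive) motion. The immobile fraction
threshold (0.1 µm² s⁻¹) is user-adjustable and not a measured value.
Simulated ensembles at the measured medians (0.19 vs 1.6 µm² s⁻¹, 500
tracks each) separate at p < 10⁻⁴ with a median ratio ≈ 8.4.

## 10. Experiment sizes and limitations

The shipped desk profile uses one synthesized network, 10–20 cells per run,
20–30 simulated minutes, 50 replicates per model for the comparison, and a
150 × 20 emulation design — sizes chosen so the full suite runs on a
single CPU in minutes while every qualitative result (small-world topology,
model-1 scanning dominance, the optimization skew directions and objective
conflict) is reproduced. The full-scale profile (200 comparison replicates,
3000 × 100 design) is configuration, not new code. Known limitations: the
front's parameter marginals at desk scale are noisier than at full scale
and their skew-direction readout depends on the documented prior box; the
meandering-index emulator is the weakest; and the spatial-autocorrelation
comparison treats whole-domain simulated fields, whereas imaging analyses
crop to follicles, so absolute D_uncorrelated values are not comparable
across those two settings — only within-setting contrasts are used.
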