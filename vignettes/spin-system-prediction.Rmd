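---
title: "Predicting full NMR spin systems with conformer-ensemble graph networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting full NMR spin systems with conformer-ensemble graph networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A solution NMR spectrum of a small molecule is fully determined by its
*spin system*: one chemical shift per magnetically active nucleus (ppm) and
one scalar coupling per nucleus pair (Hz).  `spinsys` predicts both from 2D
structure alone: the molecule is embedded into an ensemble of 3D conformers
by seeded knowledge-based distance geometry (ETKDG), each conformer gets a
single MMFF94 optimization step and a Boltzmann population weight, and
ensemble-averaged geometric statistics enter a graph neural network that
reads out per-atom shifts (¹H, ¹³C) and per-pair couplings (¹J~CH~, ²J~HH~,
³J~HH~, ⁴J~HH~) with per-prediction uncertainties.

The ensemble view matters physically: an NMR acquisition is long relative
to conformational motion, so observed parameters are population-weighted
averages over conformers, and stereoisomers — identical graphs with
different geometry — have different spectra.  Purely topological models
cannot see either effect.

## Featurization

Three blocks are produced per molecule (explicit hydrogens everywhere,
atoms capped at 128, elements restricted to H/C/O/N/F/S/P/Cl):

* **x** (`N × f_v`): element one-hot, scaled atomic number, default and
  total valence, formal charge, Gasteiger partial charge, aromaticity,
  ring-size flags (3–8), attached-hydrogen count.  Gasteiger charges were
  chosen as the partial-charge method; any per-atom scheme would do, but
  they are fast, deterministic and standard.
* **G_adj** (`N × N × 5`): one "any bond" slice plus one slice each for
  single, double, triple and order-1.5 bonds.  Aromatic bonds populate the
  order-1.5 slice and are *not* kekulized, so aromaticity is a first-class
  bond class rather than an artifact of a chosen Kekulé structure.
* **G_feat** (`N × N × 14`): Boltzmann-weighted mean interatomic distance;
  a Gaussian basis expansion of the distance distribution (8 centers
  evenly spaced 0.5–4.0 Å, shared width σ = 0.5 Å, each basis value
  averaged over conformers with the ensemble weights — this captures
  multimodality, e.g. anti/gauche torsional populations, that a mean
  distance alone would hide); for atom pairs sharing a bonded neighbor,
  the weighted mean subtended angle with a presence flag; and for pairs
  at bond-path length 3, the Boltzmann-averaged torsion statistics
  ⟨cos θ⟩ and ⟨cos²θ⟩ of the connecting dihedral with a presence flag.
  The torsion statistics are the sufficient statistics of any
  Karplus-type angular dependence — the physics that makes vicinal
  couplings conformation-sensitive — and extend to path-3 pairs what the
  angle features provide for path-2 pairs.  Without them, the ensemble
  information a vicinal coupling needs is recoverable only by combining
  the distance bases of all six pairs of the H–C–C–H fragment, which a
  small network does poorly (we measured a ~1.7× gap to the label noise
  floor that the torsion statistics close).

Boltzmann weights use T = 298.15 K and the MMFF94 energies after the
single optimization step, computed with the minimum-energy shift so the
weights are invariant to any constant added to the energies.  Conformer
embedding is retried once with random-coordinate initialization before
failing.  All of this sits behind `feature_config()`; a hash of the config
travels with every trained model, and prediction refuses inputs featurized
under a different config.

## The network

Two layer types run side by side on the same inputs.

**Message passing layers** lift `x` once per adjacency slice, multiply by
that slice, and collect the per-slice messages with a linear map, followed
by ReLU and per-vertex layer normalization.  The slice stack is the five
bond-class matrices plus optional integer powers of the any-bond matrix
(default {2, 3}: messages across 2 and 3 bonds in one step) plus an
identity slice for self-loops.

**Decode layers** maintain a dense `N × N` edge state initialized from
`[G_adj, G_feat]`.  Each layer first updates the vertex state with a GRU
whose input aggregates the edge state over the neighbor dimension as
three concatenated channels: the configured all-pairs reduction (mean by
default; sum and max selectable), the mean over bonded pairs, and the
mean over geminal (bond-path-2) pairs.  The two local channels preserve
bond and angle geometry that the all-pairs mean dilutes by 1/N.  The
layer then
updates the edge state with a second GRU whose input is a linear map of
the two endpoint vertex states.  The edge state is exactly symmetrized by
transpose-averaging after every layer, so predicted couplings satisfy
J(i,j) = J(j,i) by construction rather than approximately.

The final message passing and decode vertex states are concatenated and
fed to per-head shift readouts; the final edge state feeds per-head
coupling readouts (one output channel per coupling class and label
channel).  Heads are small residual blocks plus a linear output.

Internally a batch of molecules is packed block-diagonally: vertices into
one `M × f` matrix with sparse block-diagonal adjacency, and the edge
state keeps only within-molecule pairs (`E = Σ N_b²` rows).  No padding is
materialized, so cross-molecule pairs cannot leak into aggregation,
normalization statistics or the loss.  The dense layer math runs in
compiled (Armadillo) kernels; a pure-R reference implementation of the
identical computation ships alongside and the test suite asserts
bit-level agreement between the two, plus finite-difference correctness
of every gradient.

Shift targets are standardized per nucleus class and couplings per
coupling class (training-set mean/SD); predictions are de-standardized at
output.  This keeps ¹³C (~0–200 ppm) and ⁴J~HH~ (~0–1 Hz) on comparable
loss scales.

## Uncertainty by bootstrap heads

All heads share the trunk; each head has its own final layers.  Every
training molecule is assigned a fixed subset of heads — each head included
independently with probability `p_include` (default 0.5) via a hash of
(molecule id, head, seed), with a forced fallback so no subset is empty —
and the loss for that molecule is computed on the subset mean.  The
assignment is a pure function of the id, so it is stable across runs and
epochs; we chose fixed-per-molecule subsets over per-epoch redraws because
it is the simplest scheme under which each head sees a well-defined data
subset (the per-epoch variant is a sensitivity question worth exploring).
At test time all B heads run; the prediction is their mean and the
uncertainty is the sample standard deviation (denominator B − 1, exactly 0
for B = 1, so B = 1 reduces to a plain single-model trainer).  B defaults
to 10 for production use; the bundled experiments use B = 4 to keep
runtimes short.

## Joint experimental / ab initio training

Experimental labels are what we want to predict but carry misassignments
and noise; ab initio labels are clean but systematically offset.  The
model therefore has two output channels per target (experimental, ab
initio) sharing everything up to the final layer, trained with

L = L_a + [λ / (|φ_a − φ_e| + 1 ppm)] · L_e

per dual-labeled atom, where L_a/L_e are the base losses (absolute error
by default, Huber selectable) on the ab initio / experimental channel and
φ_a/φ_e the labels.  The two channels are coupled residually: the head
outputs the ab initio prediction and a zero-initialized correction, and
the experimental channel is their sum.  This matters for label transfer:
representation directions that only occur in experimentally-unlabeled
chemistry receive no experimental gradient, and with independent output
columns they would stay at random initialization — the experimental
channel would be *worse* there than the ab initio one.  With the
residual coupling it falls back to the ab initio prediction exactly
where it has no signal of its own (we measured the small-ring transfer
error dropping from 0.79 to 0.22 ppm on fixtures).  Agreement between the label sources up-weights the
experimental channel; disagreement (likely experimental error) shifts
weight to the clean channel.  Entries with only one label use that
channel's base loss directly, and λ = 0 reduces *exactly* to
ab-initio-only training on dual-labeled atoms (a unit test asserts this
identity).  The 1 ppm denominator offset is fixed; for couplings the
offset is expressed in Hz and the weighting is off by default (the
experiments here concern ¹H shifts).  Absolute error was chosen as the
base loss to match MAE reporting.

`ring_partition_experiment()` packages the label-transfer study this loss
exists for: molecules with 3-/4-membered rings act as a region with no
experimental labels, and four configurations (experimental baseline,
experimental control without the region, direct ab initio augmentation,
disagreement training over a λ grid) are compared on held-out
experimental MAE per region.

## Training

Adam (lr 10⁻³ unless stated, β = 0.9/0.999), molecules grouped into
fixed batches after one seeded shuffle, early stopping on validation loss
with configurable patience, and a divergence guard that aborts on
non-finite loss.  All randomness — splits, initialization, head
assignment, conformer embedding — derives from one seed, and the
fixture→train→evaluate pipeline is bit-reproducible on one machine.

## Evaluation

`evaluate_spin_model()` reports, per parameter class: MAE and RMSE; the
Pearson correlation between absolute error and the bootstrap uncertainty;
MAE of the most-confident 50 % / 80 % / 100 % of predictions; and rolling
MAE and rolling 95th-percentile-error curves over predictions sorted by
uncertainty.  The rolling window is 10 % of the class size (a choice —
wide enough to smooth, narrow enough to show the trend; configurable).
All metrics are reproduced against brute-force oracles in the tests.

## Stereoisomer identification (DP4)

`enumerate_stereoisomers()` lists the input structure first, then distinct
stereo-assignments in deterministic order, capped at 8 candidates.
`dp4_probability()` scores each candidate's predicted shifts against the
reference under the published Student-t error model (¹H: ν = 14.18,
σ = 0.185 ppm; ¹³C: ν = 11.38, σ = 2.306 ppm), multiplying cumulative
tail probabilities across atoms and nuclei in log space and normalizing
over candidates.  Linear rescaling of predictions against the reference
(the canonical expectation correction) is the default; a "none" mode is
provided for ablation, and which variant a given study used can be matched
by config.  `identification_benchmark()` takes an arbitrary predictor
function, so oracle, random and model predictors are benchmarked through
the identical code path.

## The synthetic data generator

No public shift/coupling corpus is bundled; `generate_fixtures()` creates
study sets whose *statistical structure* mirrors real training data while
keeping ground truth exactly known:

* molecules from a fragment grammar (C/O/N/S chains with branches and
  F/Cl/O/N substituents, optionally fused to a 3-/4-membered carbocycle,
  optionally with a stereocenter), filtered through the same input
  envelope as real data;
* shift means that are smooth functions of local electronic and
  topological descriptors (Gasteiger charge, aromaticity, heteroatom
  neighbors, small-ring membership — the small-ring term emulates the
  upfield shift of cyclopropane protons);
* ³J~HH~ means as the Boltzmann-weighted *ensemble average* of a
  Karplus-style cosine (7.76 cos²θ − 1.1 cosθ + 1.4 Hz) over the H–C–C–H
  dihedrals of the stored conformers — parameters, not geometries, are
  what conformational motion averages in the experiment, and an ensemble
  average of a smooth function of geometry is exactly the kind of
  quantity the Boltzmann-averaged basis features can carry.  Conformer
  geometry is therefore genuinely load-bearing: a model that ignores it
  cannot reach the noise floor.  The other classes are smooth functions
  of mean distances/angles;
* two label channels: experimental = mean + noise (defaults 0.08 ppm ¹H,
  0.8 ppm ¹³C, 0.5 Hz ³J~HH~ — chosen as realistic magnitudes for a
  user-contributed experimental corpus), ab initio = mean + systematic
  offset (0.7 ppm ¹H, 3 ppm ¹³C) + small noise;
* an optional heteroscedastic mode in which molecules containing N or S
  get 3× shift noise, giving a predictable high-noise subpopulation for
  uncertainty-calibration studies.

These defaults were fixed once as the package's study conditions.  What
passing tests on fixtures does and does not show: the generator's label
functions are smooth and exactly realizable, so learnability results are
about the architecture and optimizer, not about chemistry; real spectra
add solvent/temperature effects, misassignments and reference errors that
no fixture reproduces.  Conclusions about absolute accuracy on real data
require real data.

## Problem sizes used by the bundled experiments

The acceptance-style experiments train a 2 message passing + 2 decode
layer model (vertex width 64, edge width 32, B = 4) on 2,000 fixture
molecules for the learnability and uncertainty studies; the ring-region
study trains four smaller models (width 32) on 420 molecules; the
determinism check runs a miniature end-to-end pipeline twice.  The edge-state width default
of 32 (half the vertex width) reflects that the pairwise state carries
distilled geometric information and does not need the full vertex
capacity; doubling it changes held-out MAE only marginally on fixtures.

## Numerical choices and degenerate inputs

* Layer normalization ε = 10⁻⁵; ReLU nonlinearity throughout (stated
  choices where only "non-linearities and normalization" is fixed by the
  design).
* Edge symmetrization by transpose-averaging after every decode layer and
  after the coupling readout; ties in the max aggregation break toward the
  first edge row.
* Molecules with a single atom produce a valid forward pass with no
  defined couplings; empty candidate likelihood products in DP4 fall back
  to a uniform distribution with a warning; MMFF-parameter-less molecules
  get uniform conformer weights with a warning flag.
* Standardization SDs are floored at 10⁻⁶.

## Known limitations

* Conformer generation is the runtime bottleneck, as expected for
  distance-geometry pipelines; the geometry backend is an external RDKit
  process, so a Python environment with rdkit must be on the PATH.
* Solvent and temperature effects are out of scope.
* The fixture grammar covers small acyclic + small-ring chemistry only;
  aromatic heterocycles, charged species and larger rings appear only via
  the input readers, not the generator.
* DP4 constants are the published ones; refitting ν/σ to this model's
  error distribution would likely improve identification but is
  deliberately not done, to keep the scorer exactly comparable to
  standard practice.
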