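---
title: "Predicting NMR chemical shifts from 3D structure: methods and design"
author: "ShiftGNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting NMR chemical shifts from 3D structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ShiftGNN)
```

# The problem

¹H and ¹³C chemical shifts are exquisitely sensitive reporters of molecular
structure, and their quantum-chemical prediction (GIAO shielding
calculations on DFT-optimised geometries) is accurate but takes hours per
molecule. ShiftGNN implements the machine-learning alternative: a
message-passing graph neural network that reads a 3D conformer directly —
element types plus interatomic distances — and predicts per-atom shifts in
milliseconds. Because the input is geometry rather than connectivity, the
model can distinguish diastereomers, diastereotopic groups and individual
conformers, which purely 2D descriptors cannot.

The package covers the full workflow around the network: structure and
shift-table I/O, the empirical shielding→shift scaling used to turn
computed shieldings into training labels, statistical cleaning of
experimental data against computed values, diversity-based dataset
sampling, two-stage transfer learning, Boltzmann-weighted conformer
ensembles, and structure elucidation by shift matching.

# The model

## Environment graphs

A conformer becomes a directed graph: every ordered atom pair $(i, j)$ with
$d_{ij} < 5$ Å (strict inequality) is an edge. Each edge carries the
distance expanded over a grid of radial basis functions,

$$e_{ij}[k] = \exp\!\left(-\frac{(d_{ij} - k\mu)^2}{\delta}\right),
\qquad k = 0, \dots, 255,$$

with $\mu = 0.1$ Å and $\delta = 0.04$ Å². Centres sit at $k\mu$ so the
grid covers the input range; components are in $(0, 1]$ (far-off-centre
components underflow to zero in double precision). Node features start as a
learned 256-dimensional embedding of the element type. Both the basis and
the cutoff are configurable (`rbfParams()`); a larger cutoff costs
quadratically more edges.

## Update blocks

Each of the (default three) update blocks runs an edge update, a message
pass and a node update:

* **edge update** — a two-hidden-layer residual transform of
  $[h_i \,\|\, h_j \,\|\, e_{ij}]$ (implemented as three partial linear
  maps summed, which is mathematically identical and avoids materialising
  the concatenation). With three blocks the edge-updating machinery
  comprises six hidden layers in total.
* **message** — a filter generated from the current edge feature by a
  two-layer network multiplies the sender's node features elementwise;
  messages are summed over the neighbourhood.
* **node update** — residual addition of a two-layer transform of the
  aggregated message.

Masked nodes (H atoms for the ¹H model, C atoms for the ¹³C model — one
model per nucleus, since their shift ranges differ by an order of
magnitude) pass through a dense readout of widths 256–128–64–1. All
activations are shifted softplus, $\mathrm{ssp}(x) = \ln(\tfrac12 e^x +
\tfrac12)$, which is smooth and satisfies $\mathrm{ssp}(0) = 0$.

Every operation is a function of distances and element types only, so
predictions are invariant under rigid motions and equivariant under atom
relabelling; the test suite verifies both to $10^{-5}$ ppm over hundreds of
random transformations, as well as locality (an atom beyond every
message-passing radius cannot change a prediction).

## Numerical choices

* **Near-identity initialisation.** The output layer of every residual
  branch (edge update, filter, node update) is initialised at one tenth of
  its Glorot scale. The message is a *product* of node features and
  edge-derived filters, so with full-scale initialisation the forward
  signal grows multiplicatively across blocks (we observed amplification
  by ~10³ over three blocks before any training); the damped start makes
  the stack near-identity and learning stable. Embedding rows start with
  unit variance.
* **Target standardisation.** The network learns standardised targets; the
  model stores an affine output map $\hat\delta = \mu_y + \sigma_y \cdot
  f(x)$ fixed from the labels of the *first* training stage. ¹³C shifts
  live around 100 ppm, and an MAE loss on raw ppm would spend most of the
  optimisation budget just finding the mean. Retraining stages never refit
  the scale, which keeps the freeze contracts exact.
* **Optimisation.** Adam on an MAE loss (MSE available), whole molecules
  per batch, initial rate $10^{-3}$, halved when the validation loss fails
  to improve for 10 epochs. The best-validation parameters are returned;
  ties go to the earliest epoch. The rate was chosen for the desk-scale
  regime of this package (hundreds of optimiser steps), where slower
  schedules demonstrably cannot converge.
* **Determinism.** Initialisation is a pure function of the seed; training
  is deterministic given seed, data and configuration (single-threaded
  BLAS reductions permitting — reorderings at the $10^{-15}$ level are the
  only source of drift).

# Transfer learning

Training proceeds in the cascade used for shift models of this family:

1. train on computed labels with accurate geometries;
2. retrain on experimental labels, same geometries, with **only the
   readout** optimisable (`freezeScheme("readout_only")`);
3. retrain on experimental labels with cheap force-field geometries, with
   **only the edge-update blocks** optimisable
   (`freezeScheme("edge_update_only")`) — the stage that teaches the model
   to reinterpret distorted distances.

Freezing acts at tensor granularity through the group labels every
parameter tensor carries (`embedding`, `edge_update`, `message`,
`node_update`, `readout`); frozen tensors are bitwise untouched, which the
tests assert literally. `makeFreezeMask()` reports the frozen fraction of
scalar parameters — about 97% of the default configuration under
readout-only retraining. The optimiser state restarts at each stage (the
stages optimise different objectives), and the retraining rate defaults to
one tenth of the training rate, the usual fine-tuning convention. Each
stage appends lineage metadata (parent fingerprint, scheme, data
fingerprint) that round-trips through checkpoints.

Stage 2 freezes everything except the readout, and stage 3 everything
except the edge-update tensors, including the stage-2 readout; with the
source material silent on whether the embedding belongs to the frozen set,
we freeze it in both stages, the strictest reading.

# Data preparation

* **Scaling relations.** Computed isotropic shieldings $\sigma$ map to
  shifts via $\delta = a - s\sigma$ with the tabulated coefficients
  $a = 181.40$, $s = 0.97$ for ¹³C and $a = 29.30$, $s = 0.91$ for ¹H
  (`defaultScaling()`); coefficients are overridable but never refit here.
* **Structure filters.** Neutral molecules, MW strictly below 500 g/mol,
  elements within {C, H, O, N, F, Cl, P, S}, optionally only molecules
  with fully defined stereocentres (experimental assignments for ambiguous
  stereochemistry are not trustworthy training data).
* **Diversity sampling.** Greedy farthest-neighbour (max–min) selection
  under Jaccard distance on bit fingerprints. Fingerprints come from
  ChemmineR atom-pair descriptors folded to 1024 bits by modular hashing;
  any fingerprint matrix can be substituted. The first pick is the first
  index of a seeded shuffle and max–min ties resolve to the lowest index,
  so selections are reproducible.
* **IQR cleaning.** Differences between computed and experimental shifts
  are pooled per nucleus; a pair survives iff its difference lies within
  $[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, bounds
  inclusive, quartiles by linear interpolation of order statistics
  (`type = 7`). Inclusive bounds keep degenerate all-equal data intact;
  the estimator is named in the report because quartile conventions differ
  across software. Pooling across the dataset is the reference behaviour
  (outliers are misassignments relative to the population, not to a single
  molecule); a per-molecule variant exists behind a flag for exploration.
* **Splits.** Molecule-level, seeded, disjoint and exhaustive; no
  conformer of one molecule can land in two splits.

# Conformer ensembles

Room-temperature NMR observes a fast-exchange average over conformers, so
predictions are Boltzmann-weighted:

$$w_i = \frac{\exp(-E_i / RT)}{\sum_j \exp(-E_j / RT)},
\qquad R = 1.98720425864083 \times 10^{-3}\ \mathrm{kcal\,mol^{-1}K^{-1}},$$

computed after subtracting the minimum energy (numerical stability) so the
weights are invariant to energy offsets. The temperature defaults to
298.15 K and is recorded in every result; the source material does not
state a temperature, so it is surfaced as configuration. Conformers come
from OpenBabel's systematic torsion search with MMFF94 energies, then are
deduplicated by heavy-atom RMSD after Kabsch superposition at a 0.5 Å
threshold (lower-energy member wins) — the threshold is likewise
configuration, not physics. The ensemble shift is a convex combination, so
it always lies between the per-conformer extremes.

# Structure elucidation

Candidate structures are scored against an experimental peak list by
sorting both shift lists and pairing positionally; for one-to-one matching
under mean absolute difference this sorted pairing is exactly optimal (a
rearrangement argument the tests confirm against exhaustive permutation
search). Rankings with near-identical MAEs carry a tie flag. When several
spectra must be assigned to several candidates at once, the bijection
minimising cumulative MAE is found exactly by dynamic programming over
candidate subsets — the variant that rescues cases where per-spectrum
argmins collide.

Misassignment screening compares predictions against as-assigned
experimental values per atom: structures with MAE above 3.5 ppm (strict
inequality at the boundary) are flagged and their experimental values
reordered to the MAE-optimal permutation, which for absolute costs is
again sort-based. Reordering is unconstrained by default; an optional
class-constrained mode (e.g. within CH-multiplicity classes) permutes only
within classes. Unequal list lengths are a hard error unless truncation is
requested explicitly, because silent truncation can flip rankings; the
permissive mode pairs the MAE-optimal contiguous sorted window and records
what it dropped.

# The synthetic data generator

Tests and the acceptance experiments run without any external dataset. The
generator supplies three ingredients:

* **Fixtures** (`makeFixture()`): idealized, hard-wired geometries —
  methane; anti/gauche butane; chair and boat cyclohexane (exact ring
  closure, all C–C 1.526 Å, all angles 111°); cis/trans
  1,3-dimethylcyclohexane built on one canonical atom ordering so the two
  diastereomer-like geometries share an identical bond list while their
  distance multisets differ; and a valine-like amino acid whose isopropyl
  methyls are diastereotopic. Coordinates are constructed in closed form,
  not force-field generated, so tests can never drift with an embedding
  library's version.
* **An oracle label function** (`oracleShifts()`):
  $\delta_i = b_{Z(i)} + \sum_{j \ne i,\, d_{ij} < 5\text{Å}} c_{Z(j)}
  e^{-d_{ij}/\lambda}$ with $b_C = 100$, $b_H = 5$ ppm, $c_Z = 10$ ppm and
  $\lambda = 1.5$ Å — smooth, rigid-motion invariant and genuinely
  geometry-sensitive within the model cutoff, standing in for computed
  labels. The decay length concentrates label variance inside the 5 Å
  neighbourhood the network can see, so the recovery task is well-posed by
  construction.
* **Contaminated pairs** (`makeContaminatedPairs()`): matched
  computed/experimental records whose differences are Normal(0, σ) except
  for a seeded fraction displaced by ±15 ppm, with planted indices
  recorded so cleaning procedures can be scored.

The oracle-recovery experiment trains a default-configuration ¹³C model on
200 jittered fixture conformers (coordinate jitter 0.05 Å plus random
rigid motions; split 160/20/20; 25 epochs of Adam at $10^{-3}$, eight
molecules per batch) and evaluates held-out MAE against the label standard
deviation, then asks the model to separate the cis/trans pair and the
diastereotopic methyls. These problem sizes are the package's reference
desk-scale experiment: large enough that the network must actually learn
the geometry dependence (within-fixture label variation from jitter is
comparable to the between-fixture spread it must also capture), small
enough to run routinely.

What the generator does *not* emulate: electronic effects (aromatic ring
currents, heavy-atom effects), solvent shifts, experimental noise
structure, conformer-population errors, or the scale and chemical
diversity of real shift databases. Passing the recovery experiment
demonstrates that the architecture, gradients, freezing and ensemble
machinery work end to end and that geometric information flows through the
network — it does not certify accuracy on real spectra, which depends on
real training corpora.

# Known limitations

* Pure-R training: practical for desk-scale corpora (hundreds to a few
  thousand small molecules), not for $10^5$-shift databases.
* The SDF reader requires connectivity (bond-free records are rejected by
  the underlying parser); XYZ input is the bond-free route.
* SMILES input and conformer generation shell out to OpenBabel; SDF/XYZ
  workflows have no external dependency.
* Shift referencing, solvent effects and scalar couplings are out of
  scope; so are probabilistic assignment metrics (DP4-style), for which
  the sorted-MAE machinery here would be the natural substrate.
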