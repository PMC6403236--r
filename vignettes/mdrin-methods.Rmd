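---
title: "Methods: essential dynamics and residue-network analysis in mdrin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: essential dynamics and residue-network analysis in mdrin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrin)
```

## Scope and conventions

`mdrin` implements the post-simulation analysis stages commonly applied to
molecular-dynamics ensembles of protein–nucleic-acid complexes — for
example a Toll-like-receptor ectodomain dimer bound to a double-stranded
RNA ligand: geometric stability metrics, hydrogen-bond counting,
nonbonded interaction-energy decomposition, essential dynamics, and
residue-interaction-network betweenness centrality with a
reference-versus-variant differential.  It does not run simulations; it
consumes coordinate ensembles (multi-model PDB or in-memory trajectories)
and per-atom nonbonded parameters.

Internal units are nm, kJ/mol, amu, e and ps, matching the conventions of
the major MD engines; PDB input/output converts Å↔nm.  Frames are indexed
from 1 internally and carry times `time_origin_ps + (i-1)·timestep_ps`.
Analysis windows are trailing: a `window_ns = 60` window keeps the frames
with time strictly greater than `t_end − 60 ns`, always including the
final frame.  Typical production practice is three independent runs per
system; statistics are reported per run, while covariance analysis pools
the windowed frames of all runs after fitting each to the common mean.

Coordinates are assumed whole (unwrapped).  No periodic-boundary
minimum-image correction is applied anywhere; this is a documented
limitation appropriate for the whole-molecule, post-processed ensembles
the package targets.

## Superposition and fluctuation metrics

Rigid-body superposition uses the Kabsch SVD solution with the reflection
branch corrected (determinant forced to +1), optionally mass-weighted.
Configurations with fewer than 3 atoms or collinear geometry raise a rank
error rather than returning an arbitrary rotation.

* **RMSD(t)** fits every frame to a chosen reference frame on the
  selection and records the post-fit weighted RMSD.
* **RMSF** fits the windowed frames to the *window-mean* structure.  The
  mean is obtained by one fit–average iteration (fit to the first frame,
  average, refit to that mean, re-average), which removes rigid-body
  leakage from the fluctuations.  Fitting to the first frame instead is
  available via `fit_reference = "first_frame"`; the window mean is the
  default because it is the natural centre of the fluctuation model.
  Profiles are per-residue by default (root mean square over the
  residue's selected atoms), matching how such profiles are plotted.
* **Radius of gyration** and **centre-of-mass distances** are
  mass-weighted by default (engine convention), with unweighted variants
  behind a flag.
* **Minimum distances** are exhaustive over all cross pairs; overlapping
  selections are rejected because a self-distance of zero is never the
  intended quantity.
* **SASA** is Shrake–Rupley quadrature: 960 deterministic golden-spiral
  points per atom by default on the probe-expanded sphere (probe 0.14 nm,
  water), Bondi van-der-Waals radii keyed by element, configurable table.
  960 points keep the single-atom quadrature error well under 1%.  Note
  that with a fixed point grid SASA is rotation-invariant only up to
  quadrature (relative differences of order 10⁻³ at 120 points); tests
  account for this.

## Hydrogen bonds

Detection is geometric with the widely used engine convention:
donor–acceptor distance ≤ 0.35 nm **and** hydrogen–donor–acceptor angle
≤ 30°.  This is stated explicitly because the alternative
donor–hydrogen–acceptor ≥ 150° convention is also common; the two do not
agree bond-for-bond.  Donors are N/O atoms with a covalently bound
hydrogen, inferred once from the first frame by an H–heavy distance below
0.12 nm; hydrogens on carbon never donate; acceptors are all N and O
atoms.  Group-versus-group counts sum bonds donated in either direction
and are therefore symmetric in the two groups.

## Nonbonded interaction energies

Per-frame decomposition over *cross pairs only*:

* Coulomb: `f·q_i·q_j / r_ij` with `f = 138.935458 kJ·mol⁻¹·nm·e⁻²`,
* Lennard-Jones: `4ε_ij[(σ_ij/r)¹² − (σ_ij/r)⁶]`, σ/ε combined by
  Lorentz–Berthelot (default) or geometric rules.

The Coulomb sum is plainly truncated (optional cutoff, default none): no
reaction field or mesh-Ewald long-range term is applied, because such
terms are not decomposable per residue pair.  Consequently per-residue
contributions sum *exactly* to the group total — the property the
decomposition exists for — but absolute magnitudes are not comparable to
energies from Ewald-based engines.  Window statistics use block
averaging with 5 equal blocks (error = sd of block means / √5); block
averaging was chosen over a plain standard error because MD frames are
serially correlated.

## Essential dynamics

The coordinate covariance `C = ⟨(x−⟨x⟩)(x−⟨x⟩)ᵀ⟩` is accumulated over
windowed frames (pooled across runs) after one fit–average iteration on
the selection, with divisor *n* (ensemble average), unweighted by default
(mass weighting behind a flag).  The model stores the Kabsch target used
during accumulation so that projections of the training window reproduce
the eigenvalues as score variances exactly.

* **Free-energy landscape**: 2-D histogram of two PC scores over 32×32
  bins spanning the data range padded by 5%, converted to
  `ΔG = −k_B·T·ln(P/P_max)` with `k_B = 0.0083144621 kJ·mol⁻¹·K⁻¹` and
  T = 300 K by default; unoccupied bins are +∞ (rendered in CSV as the
  maximum finite ΔG + 1 with an explicit `occupied` column).  The
  representative frame is the one whose score pair is nearest to the
  centre of the global-minimum bin, ties resolving to the lowest frame
  index.
* **Covariance overlap** (Hess): on rank-k reconstructions `A_k`, `B_k`
  (k = 10 by default),
  `1 − sqrt(tr(A_k + B_k − 2(A_k^{1/2} B_k A_k^{1/2})^{1/2}) / (tr A_k + tr B_k))`.
  Numerically the distance term is evaluated as the orthogonal-Procrustes
  residual `min_W ‖A_k^{1/2} − B_k^{1/2}W‖_F²`, which is algebraically
  identical but avoids the catastrophic trace cancellation that otherwise
  limits self-overlap accuracy to ~10⁻⁷; matrix square roots zero all
  eigenvalues below 10⁻¹² of the largest so that round-off noise cannot
  contribute 10⁻⁸-sized spurious components.  The result is clipped to
  [0, 1].
* **RMSIP**: `sqrt((1/k) Σ_{i,j≤k} (v_i·w_j)²)`, invariant to eigenvector
  sign flips and basis rotations within the subspaces.
* **Porcupine** vectors for mode *m* are `± scale·sqrt(λ_m)·v_m` reshaped
  to atoms, with the two extreme structures about the model mean.

## Residue interaction network

Nodes are residues; an edge joins two residues whose closest *heavy-atom*
(non-hydrogen) cross distance is ≤ 0.7 nm in the analysed frame —
conventionally a representative frame from the free-energy landscape, not
a trajectory average (a frame-averaged consensus mode exists but is off
by default).  Edges carry the number of detected hydrogen bonds between
the two residues as an integer weight (0 allowed).

Betweenness centrality uses the Brandes single-source accumulation with
the normalisation `2/((N−2)(N−1))`, so the interior node of a three-node
path and the centre of a star both score exactly 1.  Two path semantics
are provided: hop-count shortest paths (default) and, as an explicit
*interpretation* of the bond-count weighting, Dijkstra paths with edge
length `1/(1 + hbond_weight)` (more hydrogen bonds = shorter effective
distance).  The weighted mode reduces exactly to the unweighted one when
all weights are equal.  Disconnected node pairs contribute nothing while
the normalisation keeps the global N, so centralities of a fragmented
graph are conservative.  Path ties are handled exactly by Brandes path
counting (no sampling); in the weighted mode, length comparisons use a
10⁻¹² tolerance.

High-centrality residues are selected at `C_B ≥ 0.1` (inclusive).  The
differential procedure compares a reference table with one or more
variants on identical node sets, flags residues with `|ΔC_B| ≥ 0.05`, and
reports the intersection of the flagged sets across variants — a direct
measure of how much of the perturbation pattern the variants share.  By
default all residues including nucleotides are nodes; a protein-only
restriction is available through the selection argument.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline needs, deterministically
given a seed (each takes an explicit seed and restores the caller's RNG
state):

* **Toy complexes** (`make_toy_complex`): two arc-shaped ("horseshoe")
  protein chains stacked across a dimer interface around a central
  rigid-ladder duplex ligand, with hydrogen bonds *planted by
  construction* at three kinds of interaction sites — an N-terminal
  ligand site, a C-terminal ligand site, and the chain–chain dimer
  interface.  The default architecture plants 3 + 2 ligand bonds per
  protein chain and 1 dimer-interface bond, a desk-scale echo of the
  two-binding-sites-plus-dimer-interface topology of receptor–dsRNA
  complexes.  Planted pairs are collinear at 0.30 nm (inside the
  0.35 nm/30° criteria with margin); all other cross-group
  donor–acceptor distances exceed 0.4 nm, and the construction is
  verified by running the detector — an infeasible spec raises an error
  rather than generating a wrong truth.  Residues are idealised (5-atom
  amino acids, 6-atom nucleotides): sufficient to exercise every
  geometric, energetic and network operator while keeping fixtures
  readable.  Coordinate jitter (±0.008 nm) varies with the seed; planted
  truth never does.
* **Gaussian trajectories** (`make_gaussian_trajectory`): frames are
  `reference + Σ_m a_{t,m}·v_m + ε` with orthonormal planted modes,
  `a ~ N(0, variance_m)` and isotropic noise — a low-rank Gaussian model
  of the fluctuation statistics that covariance analysis assumes.  The
  default planted spectrum used throughout the tests is (0.9, 0.3,
  0.1) nm² over backbone atoms with 0.005–0.01 nm isotropic noise, sized
  so that the planted modes dominate the spectrum the way a handful of
  collective motions dominate a converged production window.
* **Graph and parameter fixtures** with known topology/centrality and
  bounded random charges (q ∈ [−1, 1] e, σ ∈ [0.25, 0.4] nm,
  ε ∈ [0.1, 1] kJ/mol).

What passing tests on these data do **not** show: force-field realism,
secondary structure, solvent effects, anharmonicity or state transitions.
The generators validate the *operators* (exact planted truths, parameter
recovery within stated tolerances), not the biology.

## Problem sizes and tolerances in the test suite

The suite runs at desk scale, chosen to make the statistical tolerances
meaningful while keeping a full run in minutes: PCA parameter recovery
uses 5000 frames (eigenvalue tolerance 5%, subspace RMSIP ≥ 0.99);
oracle-exact checks (hydrogen bonds, betweenness, energies, minimum
distances) use exact or 10⁻¹⁰-level comparisons on randomized fixtures;
the end-to-end pipeline determinism check uses two complexes × three
runs × 500 frames and asserts bit-identical CSVs on re-run.  The
acceptance script (`scripts/acceptance.R`) recomputes the same quantities
from scratch under a caller-supplied seed.

## Known limitations

* No periodic-boundary handling; inputs must be whole molecules.
* Truncated Coulomb only: group energies are decomposable but not
  comparable in absolute magnitude to mesh-Ewald totals.
* SASA uses a fixed quadrature sphere (not bit-comparable with other
  tools' dot densities, and rotation-invariant only to quadrature
  accuracy).
* Binary trajectory formats (XTC/TRR/DCD) and mmCIF are out of scope;
  multi-model PDB is the interchange format.
* The weighted-path semantics of a bond-count-weighted residue network
  are an interpretation (`ℓ = 1/(1+w)`), clearly flagged; the unweighted
  mode is the default.
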