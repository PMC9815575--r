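---
title: "Inferring allosteric mechanisms from paired MD ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring allosteric mechanisms from paired MD ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopath)
```

## The problem

A point mutation far from a protein's functional site can reshape the
conformational ensemble of that site. `allopath` compares two
molecular-dynamics ensembles — a reference system and a perturbed one
(e.g. wild type vs. a distal point variant of a multi-domain signalling
protein such as a STAT transcription factor) — and asks three
questions:

1. **Which conformational states does each system visit, and how
   often?** (landscape + kinetics)
2. **Which inter-domain contacts stay rigid enough to transmit a
   mechanical signal?** (rigid core)
3. **Along which chain of residues does the perturbation actually
   propagate, and which specific interactions switch?** (PRE network +
   differential hydrogen bonds)

Each stage is an exported function operating on an `ensemble_set`
(multi-replica trajectories in Angstrom over a shared `topology`), so
the pipeline can be run whole (`run_pipeline()`) or stage by stage.

## Models and estimators

### Conformational landscape

Frames are featurized as residue-pair distances: mass-weighted
center-of-mass distances for binding-pocket residues
(`com_pair_distances()`), or CA–CA distances for inter-domain pairs
selected by a 1 nm contact criterion applied in *both* systems and
intersected (`select_interdomain_ca_pairs()`). Principal components
are computed from the raw covariance of the centered features
(`fit_pca()`); features are not standardized because they share one
unit (Angstrom) and relative amplitudes are the signal. The fit is on
the *combined* two-system frame set by default, so both systems live in
one coordinate system and macro-states can be compared across systems.
Eigenvector signs follow a fixed convention (largest-magnitude loading
positive) so projections are reproducible across platforms.

### Kinetic macro-states

The 2-D projection is discretized into micro-states by Ward
agglomerative clustering (`cluster_microstates()`, default 300
micro-states). For tractability the hierarchy is built on an evenly
spaced subset of at most `max_fit_frames` frames (default 5000) and all
frames are assigned to the nearest cluster mean; assignment of new data
uses the same rule, so labels are reproducible from the serialized
centers.

Transitions are counted with a sliding window at lag $\tau$ strictly
within each replica (`count_transitions()`); replica and system
boundaries are never crossed. The transition matrix uses the
symmetrized reversible estimator

$$P_{ij} = \frac{C_{ij} + C_{ji}}{\sum_k (C_{ik} + C_{ki})},$$

with the stationary distribution $\pi_i \propto \sum_k (C_{ik} +
C_{ki})$, so detailed balance $\pi_i P_{ij} = \pi_j P_{ji}$ holds
exactly by construction and the spectrum is real. Before estimation the
count graph is trimmed to its largest connected component (the
estimator is ill-posed otherwise; trimmed micro-states map to `NA`).
Implied timescales $t_i(\tau) = -\tau / \ln \lambda_i(\tau)$ are
emitted over a lag list so the user can pick the lag where they
plateau, mirroring the usual human-in-the-loop lag selection.

Macro-states come from PCCA+ on the leading right eigenvectors
(inner-simplex vertex construction; crisp assignment by maximum
membership, ties to the lower index). Macro-states are renumbered by
descending occupancy so names are stable across runs. Counts are pooled
over all replicas of both systems: macro-states must be shared objects
for per-system occupancy (`macrostate_occupancy()`) to be comparable.

### Rigid core

For every selected inter-domain CA pair, `pair_variability()` reports
the mean and the population (N-denominator) standard deviation of the
distance pooled over all frames of all replicas of *both* systems, and
ranks pairs by ascending deviation; `rigid_core_selection()` keeps the
`k` least-deviating pairs (default 200, the breadth appropriate to a
full-size protein with thousands of candidate pairs). Pooling across
systems is deliberate: a pair is "rigid core" only if it is quiet in
both ensembles.

### PRE pathway network (REDAN)

For each residue pair in persistent contact, the CA-distance
distributions $p$ (reference) and $q$ (perturbed) are estimated as
fixed-width histograms (default 0.1 Angstrom) on a shared support
padded by one bin, with a pseudocount of $1/n$ per bin; the
perturbation relative entropy is the symmetrized Kullback–Leibler
divergence

$$\mathrm{PRE} = \tfrac12\left(D_{KL}(p\|q) + D_{KL}(q\|p)\right)$$

in nats. The network connects two residues when the *largest* CA–CA
distance observed over all analyzed frames of both systems stays below
10 Angstrom (configurable to a quantile for robustness against single
outlier frames); edges are weighted $1/\max(\mathrm{PRE},
\varepsilon)$ with $\varepsilon = 10^{-6}$, so unresponsive pairs get
enormous weights and cannot conduct a pathway, which is the method's
intent. `shortest_allosteric_path()` runs Dijkstra with deterministic
tie-breaks (fewer hops, then lexicographic residue order); alternatives
are available as Yen-style loopless paths.

The histogram estimator, bin width, and pseudocount are package
choices: a symmetrized KL on finite samples requires *some*
regularization, and a fixed-width histogram with an explicit
pseudocount is deterministic and easy to reason about. The estimator
has a small positive bias (about +0.02 nats on 10^5 Gaussian samples
at 0.05-Angstrom bins), which cancels in the ranking-style comparisons
the network makes.

### Hydrogen-bond networks

`detect_hbonds()` applies the geometric criterion: bond present in a
frame when the H...acceptor distance is at most 2.5 Angstrom and the
donor–H...acceptor angle is at least 120 degrees; bonds are kept when
present in at least 10 percent of frames (all configurable). Detection
requires explicit hydrogens with known covalent parents — the package
never infers implicit hydrogens. Salt bridges between amine and
carboxylate groups satisfy the same rule and are reported as hydrogen
bonds. Detection runs globally and rates are then stratified by
macro-state (`hbond_rates_by_state()`); bonds are keyed by donor and
acceptor heavy atoms so rotamer-equivalent hydrogens aggregate.

The differential network against a reference macro-state uses a ratio
rule: gained in state $M$ when $r_M \ge 1.5\, r_{\mathrm{ref}}$, lost
when $r_M \le 0.5\, r_{\mathrm{ref}}$ — deliberately asymmetric, as a
"50 percent higher / 50 percent lower" rule is. A floor
(`min_rate = 0.05`) suppresses ratios of near-zero rates, which would
otherwise classify noise. `conserved_hbonds()` reports bonds at or
above a rate floor (default 0.5) in *every* macro-state.

### Geometry utilities

* **Helix global tilt** builds local axes from sliding windows of four
  consecutive CA atoms (successive bond-vector differences crossed,
  oriented along the chain), averages them, and reports the angle to a
  reference axis (default $[0,0,1]$) in $[0^\circ, 180^\circ]$ — not
  folded to $90^\circ$, because after global alignment the direction of
  a tilt distinguishes macro-states. On noiseless ideal helices the
  recovery is exact; on noisy data the angle estimate carries an upward
  bias that grows with per-residue noise (the mean of noisy unit axes
  tilts away from the true axis), so tilt *differences* between
  macro-states are the robust readout.
* **RMSD/RMSF** use least-squares superposition; RMSF superposes each
  replica onto its own first frame's CA set and averages per-residue
  fluctuations over replicas with a standard error (flagged 0 for a
  single replica). For isotropic per-coordinate jitter $\sigma$, RMSF
  approaches $\sigma\sqrt{3}$.
* **Ramachandran classification** uses rectangular regions (alpha:
  $\phi \in [-100,-30]$, $\psi \in [-80,-5]$; beta: $\phi \in
  [-180,-45]$, $\psi \in [90,180] \cup [-180,-150]$), overridable —
  region boundaries are a convention, not a measurement.
* Two-sample comparisons report the Welch (unequal-variance) $t$ test
  and the two-sample Kolmogorov–Smirnov test; Welch is the safer
  default when variances differ between macro-states.

## The synthetic benchmark and what it does (not) show

`synthetic_spec()` + `generate_ensembles()` produce a bead-per-residue
(CA-only) four-domain model protein — three ideal helices and one
extended strand on a bundle — with every downstream signal planted:

* **Kinetics.** A hidden Markov chain over $K$ metastable states
  (default $K = 3$, self-transition 0.97 per frame) emits frames as
  state mean + isotropic Gaussian noise ($\sigma = 0.4$ Angstrom per
  residue); each state displaces a mobile sub-domain (3.5 Angstrom per
  state index) and tilts a helix (6 degrees per state). Replicas start
  from independent stationary draws.
* **Rigid core.** The residues of the closest CCD–DBD interface pairs
  receive strongly reduced noise (0.04 Angstrom); ground truth is the
  set of their cross pairs within the same 10 Angstrom range the
  selection operates in.
* **Allosteric path.** In the perturbed system only, consecutive
  residues of a strand segment are displaced alternately by
  $\pm\delta/2$ along the strand axis (default $\delta = 2$ Angstrom),
  so consecutive path-pair distance distributions shift by $\delta$
  between systems while next-nearest pairs are untouched. This
  concentrates PRE on exactly the consecutive planted edges: detour
  edges through off-path neighbours see at most half the shift (a
  quarter of the divergence) and cost two edges instead of one, so the
  minimal-weight path is the planted chain by construction, not by
  accident.
* **Hydrogen bonds.** Donor/H/acceptor pseudo-atoms ride on the
  residue beads; per frame the hydrogen is placed at 1.9 Angstrom from
  the acceptor on the donor–acceptor axis (present) or at 4.5 Angstrom
  (absent), with per-state Bernoulli presence probabilities.

All randomness flows from one seed; equal specs generate bit-identical
ensembles. Default sizes (2 systems x 3 replicas x 5000 frames, 120
residues) are the validation conditions used by the package's
acceptance checks; the two-state relaxation check uses one replica of
50 000 frames over a 40-residue model, and the closed-form PRE check
uses 10^5 Gaussian samples.

What the generator does **not** emulate: explicit solvent, side-chain
chemistry, anharmonic wells, correlated backbone motion along the
chain, force-field physics, or realistic transition-state geometry.
Passing the benchmark therefore demonstrates that the estimators
recover what they are defined to recover under their own statistical
assumptions — it does not certify performance on real trajectories,
where featurization choices and sampling adequacy dominate.

## Numerical choices and degenerate inputs

* Internal unit is Angstrom everywhere; readers rescale
  nanometre-based trajectories on load (one canon avoids silent
  factor-of-ten errors between the 10 Angstrom and 1 nm cutoffs).
* Residue numbers are preserved from the input PDB (author numbering);
  all reports use them.
* Replica boundaries are first-class: nothing treats the concatenation
  as one time series except where explicitly pooled (PCA fitting,
  variability pooling), and transition counting never crosses them.
* Constant feature columns are kept and reported, not silently
  dropped; zero-variance identical samples make the $t$ statistic
  undefined and are flagged rather than guessed.
* `discard_equilibration()` drops whole frames
  (`floor(discard / dt)`); it is the identity at 0 and composes over
  consecutive discards on the frame grid.
* PCCA+ with `n_macro` equal to the number of micro-states degenerates
  to the identity coarse-graining; a request beyond the apparent
  spectral gap warns but computes.
* Dijkstra ties (equal total weight) resolve to fewer hops, then
  lexicographic order, making extracted pathways reproducible.

## Design decisions that were genuinely open

* **Domain boundaries are configuration, not code.** Real domain
  annotations live in sequence databases and differ between
  constructs; the package never hard-codes them.
* **Path plant is a constant displacement in the perturbed system**
  (not switched per hidden state): it makes the planted
  consecutive-pair shift exactly $\delta$, keeps the contact graph
  identical across systems, and makes the optimal-path argument above
  provable. A state-gated displacement would only dilute the same
  signal by the state occupancy.
* **Pooled (not per-system) deviation for the rigid core**, and
  **global H-bond detection then stratified rates**: both follow from
  treating macro-states and the rigid core as properties of the
  combined ensemble that the two systems occupy differently.
* **Micro-state hierarchy on a frame subset**: exact agglomerative
  clustering is quadratic in frames; building the tree on an even
  subset and assigning by nearest center preserves determinism and
  changes labels only at cluster boundaries.

## Known limitations

* PCCA+ memberships use the inner-simplex construction without the
  subsequent constrained optimization refinement; for well-separated
  metastable spectra (the regime the method targets) crisp assignments
  agree, but heavily overlapping macro-states may differ from refined
  implementations.
* The PRE estimator's pseudocount bias makes *absolute* PRE values
  estimator-dependent; only comparisons within one run are meaningful.
* Trajectory input is PDB topology + DCD (or multi-model PDB); other
  formats should be converted upstream.
* The helix-tilt noise bias (above) means absolute tilt values on
  noisy ensembles are upper bounds; compare distributions, not single
  values.
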