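# allopath

Allosteric mechanism inference from paired molecular-dynamics
ensembles.

A distal point mutation can reshape a protein's functional site without
touching it. Given two MD ensembles — a reference system and a
perturbed one (wild type vs. variant), each with several replicas —
`allopath` reconstructs the chain of evidence for such an allosteric
mechanism:

1. **Conformational landscape** — PCA on residue-pair distance
   features (center-of-mass pocket distances, inter-domain CA
   distances), fitted on the combined two-system ensemble.
2. **Kinetic macro-states** — Ward micro-state clustering of the 2-D
   landscape, a reversible Markov state model built with the
   symmetrized estimator
   `P_ij = (C_ij + C_ji) / sum_k (C_ik + C_ki)` (detailed balance exact
   by construction), implied-timescale lag diagnostics, and PCCA+
   coarse-graining with per-system occupancy.
3. **Rigid core** — inter-domain CA pairs ranked by pooled distance
   standard deviation; the least-deviating pairs are the candidate
   mechanical couplings between domains.
4. **REDAN pathway** — per-pair perturbation relative entropy
   `PRE = (D_KL(p||q) + D_KL(q||p)) / 2` between the two systems'
   distance distributions, a contact graph (edge iff the largest
   observed CA–CA distance < 10 Å) weighted `1/PRE`, and
   minimal-weight Dijkstra pathways from an effector residue to a
   regulatory site.
5. **Differential hydrogen-bond network** — geometric
   (distance/angle) H-bond detection, per-macro-state occurrence
   rates, bonds conserved across states, and gained/lost sets versus a
   reference macro-state under the ±50 % ratio rule.

A synthetic-data module generates two-system, multi-replica
bead-per-residue ensembles with *planted* metastable kinetics, rigid
pairs, an allosteric path, per-state hydrogen bonds and helix tilts,
so every stage can be validated against known ground truth.

## Worked example

```r
library(allopath)

# Two synthetic systems: B carries a planted perturbation along
# residues 63-88 of the linker strand
spec <- synthetic_spec(seed = 1)
gen  <- generate_ensembles(spec)

# 1. landscape: PCA of pocket COM pair distances, combined fit
pocket <- tail(spec$domain_map$domains$SH2, 24)
feats  <- combine_features(com_pair_distances(gen$A, pocket),
                           com_pair_distances(gen$B, pocket))
model  <- fit_pca(feats)
print(model)
#> pca_model (combined): 276 features; PC1+PC2 explain 43.9%

# 2. kinetics: 300 micro-states, lag 5 frames, 3 macro-states
proj  <- project_pca(model, feats)
micro <- cluster_microstates(proj, n_micro = 300)
traj  <- paste(feats$info$system, feats$info$replica, sep = "/")
tm    <- transition_matrix(count_transitions(micro$labels, 5, traj),
                           lag_frames = 5)
macro <- pcca_coarse_grain(tm, 3, microstates = micro,
                           system = feats$info$system)
print(round(macro$occupancy, 3))
#>             M1    M2    M3
#> system_A 0.334 0.336 0.329
#> system_B 0.361 0.325 0.313

# 3. REDAN: PRE network and minimal-weight pathway
g <- build_pre_graph(gen$A, gen$B)
path <- shortest_allosteric_path(g, source = 63, target = 88)[[1]]
print(path)
#> allosteric_path (26 residues, weight 3.058):
#>   63 -> 64 -> 65 -> ... -> 86 -> 87 -> 88
```

The PCA explains 43.9 % of the pooled variance in two components
(three planted metastable states displace a mobile sub-domain along
one axis); the macro-state occupancies are near-uniform because both
systems share one transition matrix; and the extracted minimal-weight
pathway is exactly the 26-residue planted path, because the
perturbation elevates PRE on precisely its consecutive residue pairs.

For real data, replace the generator with `load_topology()` +
`load_ensemble()` (PDB topology, DCD or multi-model-PDB trajectories,
nm or Å) and `discard_equilibration()`, or drive everything from one
YAML config with `run_pipeline()`, which writes TSV/JSON tables and a
run manifest per stage.

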