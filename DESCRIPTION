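Package: allopath
Title: Allosteric Mechanism Inference from Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparing two molecular dynamics ensembles (a
    reference and a perturbed system) to infer allosteric mechanisms.
    Builds conformational landscapes by principal component analysis of
    residue pair distances, discovers kinetic macro-states with Markov
    state models and Perron cluster cluster analysis (PCCA+), ranks
    conserved ("rigid core") inter-domain contacts by distance
    variability, extracts allosteric pathways from perturbation
    relative entropy (symmetrized Kullback-Leibler) residue networks,
    and compares hydrogen-bond occupancy networks between macro-states.
    Includes a synthetic trajectory generator with planted metastable
    kinetics, rigid pairs, allosteric paths, hydrogen-bond dynamics and
    helix tilts for validation against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
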