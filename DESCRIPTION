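Package: ckitraj
Title: Trajectory Analysis of Cyclin/Cdk/CKI Trimer Dynamics
Version: 0.1.0
Authors@R: person("ckitraj", "maintainers", email = "ckitraj@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing molecular-dynamics
    trajectories of Cyclin/Cdk/Cip-Kip-inhibitor ternary complexes and the
    structural consequences of inhibitor tyrosine phosphorylation. Provides
    multi-model PDB trajectory input with an atom-selection mini-grammar,
    Kabsch best-fit superposition and C-alpha RMSD series with equilibration
    trimming, geometric hydrogen-bond detection with lifetime-fraction and
    bound-episode statistics and persistent intermolecular contact networks,
    DSSP secondary-structure assignment and per-residue secondary-structure
    fractions, LCPO solvent-accessible surface area with accessibility
    classification and density estimation, centre-of-mass collective
    variables with ejection-event detection and kinase-activity inference,
    per-residue decomposition of interface binding energy under a screened
    molecular-mechanics model, k-means conformer extraction, a toy
    accelerated-MD sampler with boost-potential reweighting,
    alignment-based phospho-site conservation scoring, and a synthetic
    trimer-trajectory generator that plants machine-readable ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
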