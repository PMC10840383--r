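Package: intol3d
Title: Structure-Aware Missense Intolerance Mapping and GluD Receptor
    Pharmacology Quantification
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes regional missense intolerance on protein structures
    using a three-dimensional missense tolerance ratio (3D MTR): codon-level
    expected missense/synonymous enumeration under the standard genetic code,
    k-nearest-residue windows in space, cross-gene projection through global
    sequence alignment, chain averaging, intra-complex scoring across
    interacting proteins, and B-factor-encoded colored PDB output. Also
    quantifies ionotropic glutamate delta receptor electrophysiology and
    biophysics: sodium/NMDG difference currents, percent-of-maximum drug
    effects, Hill-equation dose-response fits (EC50/IC50), potency ratios
    with Dunnett and Welch-Bonferroni group comparisons, beta-lactamase
    surface-expression slope ratios, and adhesion-frequency estimation.
    Includes deterministic synthetic-data generators so the full pipeline
    runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
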