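Package: pspmdesign
Title: Language-Model-Restrained Fixed-Backbone Protein Sequence Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fixed-backbone combinatorial protein sequence design restrained by
    per-position amino-acid probabilities from a masked protein language model.
    Scores sequences by pseudoperplexity, builds a position-specific probability
    matrix (PSPM) from a masked-prediction provider, converts it into a
    per-residue sequence-profile restraint on a coarse design energy, and runs a
    two-round design workflow: an unrestrained first round, prediction of amino
    acid probabilities for the best first-round design, then a restrained second
    round. Includes solvent-accessibility-based layer design rules, a
    simulated-annealing packer with an exhaustive oracle, PSI-BLAST PSSM file
    interchange, worst-position audits with amino-acid grouping, and a
    deterministic generator of ideal helix-bundle test backbones with a
    synthetic masked-probability provider so the whole workflow runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    bio3d,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
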