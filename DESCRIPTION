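Package: crabReap
Title: Simulation and Quantification of Competitive Replication and
    Adduct Bypass Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An in-silico implementation of the shuttle-vector assay used
    to measure how site-specific DNA adducts affect replication in cells:
    the competitive replication and adduct bypass (CRAB) assay combined
    with restriction endonuclease and post-labeling (REAP) readout.
    Provides oligodeoxyribonucleotide sequence and monoisotopic-mass
    primitives covering O4-alkylthymidine adducts, scaffold-guided
    construct assembly, sequential Type IIS/frequent-cutter restriction
    digestion with strand-selective 5'-end label bookkeeping, gel-band
    quantification into bypass efficiencies and mutation spectra with
    replicate statistics, negative-mode ESI fragment-ion prediction for
    product verification, and a seeded synthetic-data generator emulating
    replicate gel lanes and peak lists so the whole pipeline is testable
    without wet-lab data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mzR,
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, SequenceMatching, MassSpectrometry, Software
RoxygenNote: 7.3.3
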