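Package: sumoscape
Title: Landscape Analysis of Human SUMOylation Sites
Version: 0.1.0
Authors@R:
    person("PTM", "Atlas Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for large-scale analysis of protein
    SUMOylation from mass-spectrometry evidence. Covers SUMO-remnant mass
    arithmetic and diagnostic-ion spectral prefiltering, multi-protease
    in-silico digestion for peptide search databases, decoy-amino-acid
    false localization rate (FLR) estimation with peptidoform-site
    collapsing, Gold/Silver/Bronze confidence tiering of sites merged
    across datasets, downstream characterization of lysine sets (intrinsic
    disorder, solvent accessibility, secondary structure, disease variants,
    phosphorylation proximity), iterative motif-x style motif extraction,
    and SUMO-ubiquitin crosstalk classification. A synthetic-data module
    generates proteomes, planted sites, PSM tables, spectra and annotation
    tracks so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
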