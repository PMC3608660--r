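Package: CollagenPhylo
Title: Collagen (I) Palaeoproteomic Phylogenetics from Peptide Mass Spectra
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for placing extinct taxa on the mammalian tree
    from bone collagen (I) peptide mass spectrometry. Covers in-silico tryptic
    digestion with variable-modification enumeration, monoisotopic peptide and
    b/y fragment-ion mass arithmetic, peptide-mass-fingerprint (PMF) comparison
    and species-biomarker discovery, probabilistic ion scoring of tandem MS
    spectra with normal and error-tolerant database search, assembly of
    score-filtered peptide identifications into partial alpha1(I)/alpha2(I)
    chain sequences on a master coordinate system, and downstream
    maximum-likelihood (Dayhoff + gamma) and NeighborNet split-network
    phylogenetics. A seeded synthetic-data module simulates Gly-Xaa-Yaa
    collagen chains evolving on a known tree, fossil-style peptide-wise
    sequence loss, and MALDI PMF and tandem MS spectra, so the whole pipeline
    is testable end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
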