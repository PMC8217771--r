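Package: shellome
Title: Characterization of Shell Matrix Proteins from Proteomic Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing shell matrix proteins (SMPs) identified
    from mollusc shell proteomes. Detects low-complexity regions with two
    sliding-window compositional criteria (a single residue at >=50% of a
    10-residue window over >14 consecutive residues, or the two most abundant
    residues at >=40% and >=20% over >19), finds homopolymer runs such as
    C-terminal poly-Asp tails, computes molecular weight and theoretical
    isoelectric point by Henderson-Hasselbalch bisection under named pKa sets,
    applies the acidic-protein rule (Asp+Glu > 20% and pI < 3.5), classifies
    proteins into conserved-domain / LCR-containing / uncharacterized
    categories from domain annotations including BMSP-like architecture
    detection (tandem N-terminal VWA domains followed by chitin-binding
    domains), applies the two-peptide acceptance rule with extract-presence
    partitioning, overlays thresholded phosphorylation-site predictions on
    LCRs, and normalizes enzyme-linked lectin assay plates to percent of
    maximum reactivity. A seeded synthetic-data generator with recorded ground
    truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
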