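Package: dynomine
Title: Mining Dynorphin-Like Peptide Precursors from Transcriptomes and
    Quantifying Their Opioid-Receptor Pharmacology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for discovering dynorphin-like neuropeptide
    precursors in nucleotide contigs and quantifying candidate peptides at
    the kappa-opioid receptor. Sequence stages: six-frame conceptual
    translation, YGGF opioid-motif candidate selection, affine-gap
    Smith-Waterman local alignment against a preprodynorphin query with
    Karlin-Altschul E-value significance filtering, mature-peptide
    extraction, unique-hit deduplication, taxonomic profiling, and
    sequence-logo matrices with information content. Pharmacology stages:
    three-parameter logistic fits of competition radioligand-binding curves
    with Cheng-Prusoff conversion to Ki, monophasic cAMP inhibition fits
    with reference normalization, and BRET beta-arrestin-2 recruitment
    quantification by windowed-mean ligand-induced signal. A synthetic-data
    module generates transcriptome fixtures with ground-truth manifests and
    simulated binding, cAMP, and BRET datasets so the whole pipeline is
    testable offline. Peptide monoisotopic mass utilities support checking
    synthesized peptides against observed masses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
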