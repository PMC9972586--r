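Package: intronicqpcr
Title: Species-Discriminating Intronic Genomic qPCR Design and Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for intronic genomic qPCR assays that distinguish human
    from murine genomic DNA in mixed samples such as patient-derived
    xenograft (PDX) tumors. Designs primer pairs that sit entirely within
    the introns flanking a short exon (so only genomic DNA, never spliced
    cDNA, amplifies), validates them by in-silico PCR against both genomes,
    and quantifies species composition from qPCR Ct tables via delta-Ct
    fold ratios, percentage and copy-number formulas, and detection-floor
    bounds for censored wells. Includes a seeded simulator producing
    synthetic two-species genome pairs and full qPCR plates for end-to-end
    validation without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
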