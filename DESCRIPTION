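Package: xpqtl
Title: Cross-Platform Proteomics Concordance and pQTL Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing affinity-proteomics measurements of the
    same proteins across platforms (aptamer- and antibody-based), with
    attention to ancestry structure. Implements inter-platform Pearson
    correlation with Fisher-Z / Cochran's-Q heterogeneity tests across
    ancestry groups, cis/trans protein quantitative trait locus (pQTL)
    association scans with stepwise-conditional fine-mapping into
    Wakefield approximate-Bayes-factor 95 percent credible sets,
    cross-platform signal classification, detection of
    ancestry-differentiated allele frequencies, protein-altering-variant
    (PAV) adjustment with quantification of the resulting change in
    concordance and downstream associations, protein-phenotype
    epidemiological models, limit-of-detection computation from negative
    controls, and a synthetic cohort generator (Balding-Nichols
    allele-frequency differentiation, planted epitope effects) with
    closed-form correlation oracles so that every pipeline stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
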