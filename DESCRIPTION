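Package: isletpheno
Title: Nutrient-Stimulated Insulin Secretion Phenotyping and Multi-Omic
    Analysis of Human Islets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deep functional phenotyping of pancreatic islet
    perifusion experiments and paired proteome/transcriptome analysis.
    Extracts biphasic insulin-secretion features (segment AUC, first and
    second phase, peak rate, time to peak) from perifusion traces,
    classifies fatty-acid and amino-acid hyper-responder donors, contrasts
    non-diabetic and type 2 diabetic donor groups, and links donor traits
    to molecular data through differential abundance, covariate-adjusted
    regression, signed weighted co-expression networks with topological
    overlap and module eigengenes, RNA-protein concordance (including
    rank-rank hypergeometric overlap), marker-based cell-type composition
    scores, and a synthetic donor-cohort generator that emulates the
    statistical structure of such studies for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
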