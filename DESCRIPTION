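Package: reasonscore
Title: Composite Epigenetic and Clinicopathologic Risk Scoring for Early-Stage Oral Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates a composite 5-year mortality risk score for
    early-stage (I/II) oral squamous cell carcinoma that combines a
    recursive-partitioning integer score over ten clinicopathologic factors
    with a methylation-signature score derived from Illumina 450K array data.
    Implements the full discovery pipeline: an auditable probe-filter cascade
    (sex chromosomes, SNP-associated, gene-unmapped, detection p-value,
    cross-reactive, uninformative-beta, top-variance stages), surrogate
    variable estimation by residual-matrix SVD with an outcome-correlation
    exclusion rule, empirical-Bayes moderated-t differential methylation with
    Benjamini-Hochberg selection, beta-value state-transition risk calls
    (unmethylated / hemi-methylated / fully methylated), concordance-index
    evaluation with bootstrap intervals, expression-methylation correlation,
    and hypergeometric over-representation analysis. A bundled synthetic-data
    generator emulates the cohort, array, and expression structure the
    pipeline assumes so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    fgsea,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
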