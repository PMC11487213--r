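Package: pcnet
Title: Phenotypic Comorbidity Networks from Hospital Discharge Diagnoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comorbidity pattern analysis of thyroid-disease
    inpatient cohorts from long-format ICD-10 discharge-diagnosis tables.
    Implements the full analysis chain: cohort cleaning (adult thyroid-disease
    encounters, chapter exclusions, minimum diagnosis counts, rare-disease
    removal), prevalence estimation with confidence intervals, subgroup
    difference and enrichment statistics, age-profile trend and K-means
    clustering, construction of weighted phenotypic comorbidity networks using
    the cosine co-occurrence index with a Pearson-significance-matched cutoff,
    structural network metrics and weighted PageRank importance, and
    subgroup-network comparison via abundant connections. A synthetic
    electronic-medical-record cohort generator with known ground truth
    (marginal prevalences, sex and age effects, planted pairwise
    co-occurrence) makes every stage testable without access to restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
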