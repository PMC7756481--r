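Package: PhenoVarRank
Title: Phenotype-Driven Prioritization of Rare-Disease Exome Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated prioritization of annotated exome variants for rare
    Mendelian disease diagnosis. Variants are filtered on population allele
    frequency, classified under ACMG/AMP evidence rules combined into a
    Bayesian posterior probability of pathogenicity, and paired with
    candidate diseases whose phenotype similarity to the patient is scored
    over an HPO-style ontology using the maximal depth of common ancestor
    terms. Disease-variant candidates are stratified into three tiers by
    posterior and ranked within tier by phenotype similarity, producing a
    curation-ready report. Includes a synthetic-fixture generator (toy
    ontologies, knowledge bases, patients and spiked exomes) so the whole
    pipeline can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
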