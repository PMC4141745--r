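Package: oquare
Title: Structural Quality Metrics and Score Aggregation for OWL Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes twelve structural and axiomatic quality metrics on
    OWL 2 class hierarchies (depth of inheritance, cohesion, annotation
    richness, property richness and related measures adapted from
    object-oriented software metrics), maps them onto a 1-5 quality scale
    through configurable threshold bands, and aggregates them by weighted
    averages into 29 quality subcharacteristics and 7 characteristics in
    the OQuaRE (SQuaRE-based) quality model.  Ships a synthetic-ontology
    and trial-cohort generator emulating a crossed training design
    (students by topics by tasks, trained and untrained arms, gold
    standards), together with the corresponding evaluation pipeline:
    balanced subsampling, two-way ANOVA with interaction, per-topic
    t-tests, distance-to-gold matrices, Ward and k-means clustering, and
    principal component ordering of subcharacteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'owl-parse.R'
    'owl-write.R'
    'paths.R'
    'metrics.R'
    'quality-model.R'
    'scoring.R'
    'generate.R'
    'cohort.R'
    'pipeline.R'
    'cli.R'
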