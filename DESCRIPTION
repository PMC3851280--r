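Package: castriage
Title: Rule-Based Clinical Exome Variant Triage for Childhood Apraxia of Speech
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tertiary whole-exome analysis toolkit for rare pediatric motor
    speech disorders, centred on childhood apraxia of speech (CAS). Implements
    rule-based variant prioritization over annotated exome variant tables
    (multi-database allele-frequency deprioritization, consequence-based
    impact classes, in-silico predictor consensus, read-support filtering,
    neutral-polymorphism exclusion and known-gene rescue), ACMG-style clinical
    report-category assignment (likely pathogenic, VUS, VUS in a gene of
    uncertain significance), cohort-level reporting including two-gene
    ("two-hit") candidate detection, missing-data-adjusted phenotype rates,
    cost-per-diagnosis arithmetic, and a seeded synthetic annotated-exome
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
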