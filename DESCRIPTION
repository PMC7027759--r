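Package: monoscreen
Title: Discriminating Monogenic from Type 1 Diabetes with a Genetic Risk Score
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening paediatric diabetes cohorts for monogenic
    diabetes using a nine-SNP Type 1 diabetes genetic risk score (GRS).
    Computes the ln(odds ratio)-weighted allele score from VCF genotypes,
    maps scores to centiles of a reference distribution, classifies
    GAD/IA2/ZnT8 islet autoantibody titres against fixed positivity
    thresholds, detects runs of homozygosity and applies a consanguinity
    rule, and quantifies discrimination between monogenic and Type 1
    diabetes via ROC analysis, sensitivity-constrained screening thresholds
    and number-needed-to-test. A seeded synthetic cohort generator
    reproduces the statistical structure of a consanguineous paediatric
    cohort so the full pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    vcfR,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
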