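Package: grsurv
Title: Genetic Risk Scores for Biochemical Recurrence After Radical
    Prostatectomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and evaluates weighted genetic risk scores (GRS) for
    predicting biochemical recurrence after radical prostatectomy from
    exome-chip genotypes. Provides genotype and phenotype input/output
    (VCF and TSV), marker and sample quality control including an exact
    Hardy-Weinberg equilibrium test, per-SNP case-control association
    with allelic and logistic odds ratios, p-value based panel selection,
    ln(odds ratio) weighted scoring, Kaplan-Meier / log-rank / Cox
    proportional-hazards survival analysis by score group, paired
    (DeLong-type) comparison of clinical versus clinico-genetic model
    AUCs, and a cohort simulator with Hardy-Weinberg genotypes, logistic
    susceptibility and proportional-hazards recurrence times for
    end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
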