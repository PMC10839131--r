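Package: clonalCI
Title: Clonality-Index Classification of Multiple Synchronous Lung Cancers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Distinguishes independently arising multiple synchronous lung
    cancers (MSLC) from intrapulmonary metastasis (IPM) in patients with two
    tumor lesions. Shared somatic mutations between the two lesions are scored
    against a reference-cohort prevalence catalog with a binomial
    co-occurrence model; the clonality index (CI) is the -log10 probability of
    observing all shared mutations by chance. A decision cutoff is calibrated
    by simulating clonally related and unrelated lesion pairs from the
    reference cohort and maximizing classification accuracy over repeated
    simulations. Includes MAF/VCF ingestion with canonical mutation keying,
    a mutational-landscape summary, a seeded synthetic-cohort generator with
    ground truth, and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pROC,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
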