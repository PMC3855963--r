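Package: ismvar
Title: Informational Spectrum Classification of Amino Acid Substitutions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Feature-based classification of protein missense variants by the
    informational spectrum method (ISM). Protein sequences are encoded by the
    electron-ion interaction potential (EIIP) of each residue, transformed
    into an energy-density (informational) spectrum by discrete Fourier
    analysis, and each substitution is scored by the deviation of its spectrum
    from the wild type. A discriminating spectral frequency is selected by
    sequential Mann-Whitney testing in descending order of wild-type
    amplitude, and variants are called deleterious or neutral against the
    wild-type amplitude at that frequency. Includes domain-interval
    annotation, evaluation utilities (confusion metrics, ROC/AUC, Fisher's
    exact test), ingestion of third-party predictor scores, and a seeded
    synthetic-data generator with a planted spectral signal for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
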