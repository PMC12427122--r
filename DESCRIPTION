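Package: mkdr
Title: Multi-Omics Drug Response Prediction with Modality Completion and Knowledge Distillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts drug sensitivity (log-IC50) of cancer cell lines from
    multi-omics profiles (gene expression, copy number variation, mutation)
    and drug structures (SMILES). Implements self-attention encoders per
    omics modality, a bi-directional recurrent SMILES encoder, cross-modal
    attention fusion with the drug as query, variational-autoencoder
    completion of missing omics modalities from gene expression, and
    teacher-student knowledge distillation so a student model trained on
    incomplete inputs approaches a full-modality teacher. Includes a
    seeded synthetic multi-omics simulator, IQR-based response
    preprocessing, stratified splitting, six-metric evaluation,
    integrated-gradients attribution, and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
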