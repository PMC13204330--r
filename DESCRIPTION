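Package: cgmdd
Title: Contrast-Guided Multi-Modal Dataset Distillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses a labeled multi-modal image dataset into a small learnable
    synthetic dataset by jointly optimizing a gradient-matching distillation loss and a
    hierarchical cross-modal contrastive (InfoNCE) loss under cosine-annealed loss-weight
    schedules. Provides a partially-shared multi-modal encoder (modality-specific stems,
    shared trunk, modality-specific heads), a bi-level distillation loop with a proxy
    classifier, a registered multi-modal synthetic cohort generator for end-to-end testing,
    and an evaluation suite covering accuracy/macro-F1, compression-ratio and
    images-per-class sweeps, label-ratio studies, missing-modality robustness, and
    cross-architecture generalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
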