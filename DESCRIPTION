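Package: retinapair
Title: Multi-Modal Contrastive Pre-Training for Paired Fundus and OCT Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contrastive pre-training of paired 2D fundus-image and 3D OCT-volume
    encoders with InfoNCE (CLIP-style) and modern-Hopfield InfoLOOB (CLOOB-style)
    objectives, together with uni-modal self-supervised baselines (SimCLR, BYOL,
    VICReg), cross-modal retrieval evaluation with exact binomial confidence
    intervals, downstream linear probing and fine-tuning with bootstrap variance
    estimates, and a modality-interchange evaluation. A synthetic paired-cohort
    generator with shared latent structure and clinical-style labels (visual
    acuity, central subfield thickness, fluid presence, disease class, treatment
    need, conversion) makes every stage exercisable at desk scale on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    png,
    RNifti,
    jsonlite,
    yaml,
    pROC
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
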