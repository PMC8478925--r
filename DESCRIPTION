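Package: virtualCK
Title: Virtual Cytokeratin Staining and Tumor-Stroma Ratio Quantification
        for Gastric Carcinoma Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Tools for deep-learning virtual cytokeratin (CK)
        immunohistochemistry from routine H&E whole-slide images and for
        downstream tumor-stroma ratio (dTSR) quantification. Implements
        Beer-Lambert color deconvolution between RGB and the
        hematoxylin-eosin-DAB (HED) stain space, two-step (global then local)
        FFT cross-correlation registration of re-stained H&E/CK slide pairs,
        curation of paired 256x256 training patches with white-background and
        little-dyed filters, a Pix2Pix-style conditional adversarial network
        with an added HED-space L1 loss and dropout-free deterministic
        inference, mask-based dTSR scoring over pathologist hotspots with
        dichotomization at a configurable cut-off, and agreement evaluation
        (contingency tables, Cohen's kappa, rank-sum ROC/AUC) against visual
        TSR labels. A synthetic phantom module renders paired
        pseudo-H&E/pseudo-CK rasters with known tumor geometry, planted
        shifts and noise so every stage is testable without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite, yaml, png, tiff,
        EBImage
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
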