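Package: ganreg
Title: Unsupervised Adversarial Deformable Registration of Multimodal
    Brain Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised deformable registration of pre-operative magnetic
    resonance (MR) slices to intraoperative ultrasound (iUS) for brain-shift
    compensation during image-guided neurosurgery.  A convolutional
    encoder-decoder generator proposes a dense displacement field that warps
    the MR slice onto the ultrasound grid; two discriminators judge the
    warped result against each source modality; training combines the
    adversarial objectives with a mutual-information similarity loss and a
    Bayesian posterior loss, both built on differentiable joint intensity
    histograms.  The package also provides NIfTI/MetaImage and landmark IO,
    a landmark-based target registration error (mTRE) evaluation with cohort
    statistics, a synthetic multimodal MR/ultrasound slice simulator with
    known ground-truth deformations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
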