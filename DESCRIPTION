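Package: ctGAN3D
Title: 3D U-Net GAN Synthesis and Evaluation of Volumetric CT Tumor Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis of volumetric CT patches of pancreatic tumors and
    pancreas tissue with a generative adversarial network whose generator is a
    3D U-Net, together with the surrounding workflow: Hounsfield-unit
    preprocessing (isotropic resampling, soft-tissue windowing, metal-artifact
    suppression, patch extraction, rotation augmentation), three
    tumor-into-tissue blending methods (copy-paste, seamless gradient-domain
    blending, style/texture refinement), image-quality and diversity metrics
    (slice-wise FID and PSNR, a 3D Frechet distance over a cold-started seeded
    3D CNN, squared maximum mean discrepancy, pairwise MS-SSIM), and a 3D CNN
    tumor-versus-healthy classifier protocol with stratified hold-out,
    synthetic-augmentation configurations, grid search and k-fold
    cross-validation. A seeded procedural phantom generator provides
    HU-realistic volumes so the entire pipeline is exercisable without
    clinical data. All neural components run on a compact pure-R volumetric
    network engine (im2col convolutions over BLAS).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    grDevices,
    RNifti,
    EBImage,
    png,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'nn.R'
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'preprocess.R'
    'phantoms.R'
    'gan.R'
    'metrics.R'
    'blending.R'
    'classifier.R'
    'pipeline.R'
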