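Package: petdecomp
Title: Decomposition-Based CT-Free PET Attenuation and Scatter Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for CT-free attenuation and scatter correction of PET
    volumes by decomposition of the correction into a low-frequency
    anatomy-dependent correction map (ADCM) and the anatomy-independent
    tracer texture. Provides the ADCM transform and its inverse application,
    a 3D conditional adversarial network that predicts the ADCM from
    uncorrected PET, direct 2D/3D image-translation baselines, a synthetic
    attenuation-physics phantom simulator producing paired
    uncorrected/corrected volumes, and a quantitative evaluation suite
    (NRMSE, PSNR, SSIM, spherical-VOI SUV metrics, MAPE, joint-histogram
    regression, paired tests).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'adcm.R'
    'io.R'
    'metrics.R'
    'nn.R'
    'gan.R'
    'phantom.R'
    'experiment.R'
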