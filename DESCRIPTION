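Package: fieldbridge
Title: Paired Low-Field to High-Field MRI Harmonization Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired 1.5T/3T brain MRI slice stacks, rigidly realigns
    each low-field stack to its high-field counterpart, applies classical
    (bicubic, Lanczos) and learned (ESPCN, SRGAN, transformer-CNN hybrid GAN)
    super-resolution methods, and scores the results with full-reference image
    quality metrics: PSNR, SSIM, a deterministic perceptual feature distance,
    and the thresholded Intensity Differences in Pixels (IDP) metric swept over
    relative-difference thresholds. Includes the paired-design evaluation
    layer: slice-to-subject-to-cohort averaging, vendor stratification,
    repeat-scan and baseline anchor analyses, and pairwise comparisons with
    paired t-tests or subject-clustered robust standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    png,
    yaml,
    jsonlite,
    sandwich,
    lmtest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
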