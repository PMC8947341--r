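Package: hpsimri
Title: Post-Acquisition Processing of Hyperpolarized Silicon-29 MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Post-acquisition processing pipeline for hyperpolarized
    silicon-29 magnetic resonance imaging co-registered with proton
    anatomical imaging. Reconstructs magnitude images from raw k-space
    with zero-fill interpolation to the anatomical grid, estimates
    per-study background noise from the four image corners, applies
    noise-adaptive threshold denoising and region-of-interest masking,
    normalizes intensities by a silicon-oil phantom reference and by the
    universal peak across a study set, fuses the silicon map onto the
    anatomical slice as a composite overlay, and quantifies
    signal-to-noise and contrast-to-noise ratios over circular regions of
    interest with one-way analysis of variance across cohorts. Includes a
    synthetic dual-nuclei study generator (torso phantom, tumor foci,
    syringe beacon, spills, Rayleigh background, ADC-clipping artifacts)
    so the whole pipeline is testable without animal data, and a batch
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    readxl,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
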