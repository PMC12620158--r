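Package: watref
Title: Absolute MRSI Metabolite Quantification with a qMRI-Synthesized Water Reference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for absolute quantification of brain metabolite concentrations from
    2D proton MR spectroscopic imaging (MRSI). A spectroscopic water reference is
    synthesized from quantitative MRI maps (T1, T2*, B1+, water content) calibrated
    by a single-voxel STEAM water measurement, avoiding the lengthy unsuppressed
    MRSI water acquisition. The package also implements the two conventional
    water-scaling comparators (literature-value relaxation correction and full
    qMRI-based correction), CSF partial-volume correction, molal and molar
    concentration maps, point-spread-function aware reslicing of high-resolution
    maps into MRSI space, monoexponential T2 mapping, a seeded synthetic phantom
    with known ground truth, ROI aggregation and Bland-Altman method agreement
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'watref-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils-affine.R'
    'reslice.R'
    'relaxometry.R'
    'steam.R'
    'quantify.R'
    'phantom.R'
    'compare.R'
    'io.R'
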