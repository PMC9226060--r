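Package: macumap
Title: Macular Structure-Function Correlation Mapping for Glaucoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the structure-function relationship in the
    glaucomatous macula. Builds 10-2 perimetric test patterns and posterior-pole
    OCT superpixel grids, relates ganglion cell layer (GCL) and inner plexiform
    layer (IPL) superpixel thickness to visual field sensitivity through
    exhaustive Pearson correlation atlases, and derives maximum-correlation
    vector maps under a conventional (8x8 superpixels of 3 degrees, 40 averaged
    visual field units) or a localized (12x12 superpixels of 2 degrees, one unit
    per stimulus location) mapping scheme. Includes a synthetic cohort simulator
    with normative bull's-eye thickness profiles, arcuate glaucomatous damage
    respecting the horizontal raphe, retinal ganglion cell displacement,
    fixation jitter for non-tracked perimetry, and tertile-stratified disease
    severity, plus Fisher z / Wilcoxon signed-rank comparison of correlation
    distributions between mapping schemes and perimetry modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
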