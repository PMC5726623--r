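Package: glossim
Title: Rendering and Image-Statistic Modelling of Specular Highlights Under Variable Light Spread
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for studying gloss perception with
    computer-generated stimuli. Generates blob-like test meshes (subdivided
    icospheres displaced by seeded Perlin noise), ray-casts them under a
    three-point-light arrangement whose angular spread is controlled by a
    single parameter, shades them with a GGX microfacet material, segments
    the specular "gloss layer" of the rendered images, computes global
    highlight statistics and contrast measures, analyses when superposed
    specular lobes split into discernible highlights, and fits linear
    gloss-prediction models with a synthetic observer for parameter
    recovery.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
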