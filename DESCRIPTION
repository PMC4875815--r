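Package: plumalight
Title: Receptor-Noise Dichromatism, Tetrahedral Color Space, and
    Light-Regime Models of Plumage Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying avian plumage color from reflectance
    spectra and testing the light environment hypothesis. Implements the
    tetrachromatic receptor-noise model of color discrimination (distances
    in just noticeable differences between homologous male and female
    patches under ideal and habitat-specific illuminants), the tetrahedral
    color space with six whole-plumage descriptors (color span and its
    variance, convex-hull color volume, average and maximum chroma,
    brightness), and maximum-likelihood fitting of Brownian-motion and
    Ornstein-Uhlenbeck (single- and multi-regime-optimum) models of trait
    evolution on phylogenies with AICc/likelihood-ratio model selection and
    parametric-bootstrap confidence intervals. A synthetic-data generator
    emulates a museum-specimen reflectance study end to end so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
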