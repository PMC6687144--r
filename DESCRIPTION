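Package: uvfoldkit
Title: Protein Stability and DNA-Binding Analysis for UV-B Photobiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for quantitative UV-B protein photobiology
    experiments on plant MYB transcription factors: tryptophan and
    kynurenine emission-spectrum processing, Bis-ANS dye-binding
    calibration and Scatchard stoichiometry, two- and three-state
    equilibrium urea-unfolding thermodynamics by the linear extrapolation
    method, Stern-Volmer quenching fits, constrained circular-dichroism
    secondary-structure decomposition, fluorescence-anisotropy DNA-binding
    isotherms, aggregation and dynamic-light-scattering summaries, and
    promoter scanning for MYB cis-elements in TSS-relative coordinates.
    Includes seeded synthetic-data generators reproducing the statistical
    structure of each assay, so every fitting stage can be validated by
    parameter-recovery round trips.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    pracma,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
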