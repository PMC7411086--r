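Package: phaeotox
Title: Ecotoxicological Analysis Pipeline for Diatom Exposure Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for dose-response microalgal ecotoxicology
    experiments on the model diatom Phaeodactylum tricornutum: specific
    growth rates and log-logistic IC50 estimation, JIP-test parameters from
    OJIP chlorophyll-a fluorescence transients, Gauss-peak-spectra (GPS)
    deconvolution of whole-cell pigment absorbance spectra, fatty-acid
    saturation statistics including the double bond index, oxidative-stress
    assay conversions (TBARS/MDA, catalase, ascorbate peroxidase, superoxide
    dismutase), the cellular energy allocation model (Ea, Ec, CEA), and
    canonical analysis of principal coordinates (CAP) with leave-one-out
    classification. Includes a synthetic-data generator that emulates the
    full 6-treatment by 3-replicate design with known ground truth so every
    stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
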