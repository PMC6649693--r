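Package: cspmap
Title: Mapping Protein-Ligand Interaction Surfaces from NMR Titration Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for assigned 1H-15N HSQC titration series:
    weighted chemical-shift perturbations (CSPs), intensity-ratio (I/I0)
    broadening profiles with sliding-window smoothing, contiguous
    binding-patch detection, peak-trajectory linearity classification for
    exchange-regime assessment, and Calpha secondary-chemical-shift
    secondary-structure calls against a random-coil reference. Includes a
    two-state (optionally two-site) fast-exchange forward model of binding
    with ligand depletion and exchange broadening, a dissociation-constant
    fitter, and a fully seeded synthetic titration generator with a
    ground-truth answer key, so every analysis stage is testable end to end
    without deposited spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    tibble,
    ggplot2,
    yaml,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
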