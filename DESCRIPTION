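Package: pbscatter
Title: Collimator-Scattered Proton Dose, LET and RBE in Spot-Scanning
    Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale Monte Carlo study of collimator edge scattering in
    spot-scanning (pencil-beam scanning) proton therapy.  Models a scanning
    nozzle carrying a 4-cm plastic energy absorber and a patient-specific
    brass collimator, plans spread-out Bragg peak fields that deliver 2 Gy
    to rectangular targets in a water phantom, and transports protons with
    a condensed-history engine (Bethe stopping power, Highland multiple
    Coulomb scattering, Bohr energy straggling, nuclear fluence
    attenuation).  Dose and dose-averaged LET are tallied per voxel
    separately for collimator-scattered and unscattered protons, and the
    biological impact of the scattered channel is quantified with the
    McNamara linear-quadratic RBE model over a systematic sweep of target
    range, SOBP width and field size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
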