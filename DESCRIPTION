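Package: vmatqa
Title: Unsupervised Error Detection for Patient-Specific VMAT QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects delivery errors in patient-specific quality assurance of
    volumetric modulated arc therapy (VMAT) from measured-versus-calculated
    dose-difference maps on a two-plane cylindrical diode array. Anomaly in a
    dose-difference map is quantified as the Mahalanobis distance of
    variational-autoencoder latent means relative to an error-free reference
    set, and benchmarked against a supervised convolutional classifier and
    gamma-index analysis via ROC curves. Includes a synthetic dose and
    measurement simulator (simplified fluence, penumbra and attenuation model
    on a Delta4-like geometry) with injectable MLC, gantry, output and setup
    errors, so the whole pipeline runs at desk scale without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
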