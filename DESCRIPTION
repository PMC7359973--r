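Package: duospect
Title: Dual-Isotope SPECT Simulation, Reconstruction and Holmium-166 Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for quantitative dual-isotope SPECT of
    holmium-166 microspheres imaged together with technetium-99m colloid.
    Provides digital liver/lung phantoms with known activity and attenuation,
    a four-energy-window projection simulator with inter-isotope downscatter
    crosstalk and Poisson noise, OSEM reconstruction with attenuation
    correction and window-based (k-factor) downscatter correction, rigid
    registration, voxel-level beta dosimetry with volume-of-interest reports,
    and Bland-Altman, Pearson, paired t-test and Cohen's kappa agreement
    statistics for paired dose measurements.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
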