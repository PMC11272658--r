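Package: fahraeus
Title: Wall Shear Stress Estimation and Endothelial Planar Polarity
    Quantification in Small Arteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes arterial wall shear stress (WSS) from Doppler-derived
    vessel diameter and maximal blood velocity under three models: the
    theoretical Newtonian (Poiseuille) method, a corrected Newtonian method
    with an empirical centerline-to-mean velocity ratio, and a
    Fahraeus-Lindqvist plug/sheath method in which a central red-cell plug
    is surrounded by a cell-free plasma sheath so that WSS depends on plasma
    viscosity and hematocrit. Includes a linear hematocrit-viscosity model,
    method-comparison sensitivity sweeps over diameter, velocity and
    hematocrit, an image-analysis pipeline quantifying endothelial-cell
    planar polarity from two-channel fluorescence images
    (Gaussian-background thresholding, despeckling, size-filtered object
    identification, nucleus-to-Golgi vectors, orientation classes),
    ground-truthed synthetic generators for cohorts and images, and the
    statistical contracts used to report such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    tibble,
    dplyr,
    readr,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    ggplot2
Config/testthat/edition: 3
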