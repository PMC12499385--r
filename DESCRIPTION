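Package: guvactin
Title: Quantification of Actin-Induced Remodeling of Giant Unilamellar
    Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the remodeling of giant unilamellar
    vesicles (GUVs) by branched actin networks from two-channel
    (lipid/actin) epifluorescence time-lapse images.  Provides a
    synthetic-image generator with embedded ground truth, GUV contour
    segmentation and morphometry (equivalent-area diameter, Feret-based
    ellipticity, actin shell thickness and symmetry-breaking angle,
    shell/comet classification), per-degree radial fluorescence
    profiling with liquid-disordered (Ld) domain calling and
    actin-on-domain scoring, domain-coalescence time-course statistics,
    and a Saffman-Delbruck diffusion-coalescence simulator of lipid
    domains with and without steric blocking by an actin corona.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
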