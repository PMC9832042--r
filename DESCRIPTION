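Package: cartimorph
Title: Quantitative Histomorphometry of Aging Articular Cartilage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image-derived quantitative phenotyping of cartilage aging:
    a cartilage surface-roughness index from quartic-fit residuals of the
    articular surface contour, a fixed 53-descriptor nuclear shape and
    geometry vector per segmented nucleus (including moments eccentricity
    and Zernike moment magnitudes), per-cell immunofluorescence integrated
    density, principal-component analysis with loadings defined as
    variable-score correlations and top-contributor ranking, and the
    sample-level regressions linking nuclear shape, age group, and marker
    expression. Ships a seed-deterministic synthetic microscopy cohort
    generator (surface masks, DAPI nuclei images, marker channels, ground
    truth tables) so the whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    cluster,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
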