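Package: colomap
Title: Spatiotemporal Colonic Motility Mapping from Cine-MRI and Manometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies colonic motility from two simultaneously acquired
    modalities: cine magnetic resonance imaging (diameter measurement along
    a user-drawn midline, per-position linear detrending into a
    spatiotemporal residual map) and multi-channel intraluminal manometry
    (contraction detection, high-amplitude propagating contraction
    classification and propagation-velocity estimation). A coupled
    peristalsis phantom generates image series and pressure traces from a
    single ground-truth contraction-wave model, so both analysis arms and
    their cross-modality concordance can be validated end to end without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tiff,
    yaml,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
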