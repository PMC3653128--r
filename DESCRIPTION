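Package: apward
Title: Adaptive Cluster Analysis for MEG Functional Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of volumetric MEG beamformer power images for
    reliable localization of consistently active brain regions. Extracts
    frequency-band-thresholded local power maxima from pseudo-Z volumes,
    clusters the pooled activation peaks with Affinity Propagation, refines
    spatially dense clusters with Ward hierarchical clustering cut to a
    target radius, scores peak density on a millimetre mesh, and declares
    regions active from cross-subject consistency of peak scatter. Includes
    a synthetic multi-subject peak and volume simulator with planted region
    structure, bundled literature reference coordinates for reaching-related
    regions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
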