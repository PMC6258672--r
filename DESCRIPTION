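Package: junctionforce
Title: Force Inference and Ratiometric Quantification for Epithelial Junction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate relative mechanical tensions along epithelial
    cell-cell junctions from segmented tissue images by variational force
    inference (fitting a tension triangulation perpendicular to the cell
    network), to derive junctional shear stress from the tensions of
    neighbouring junctions, and to quantify junctional fluorescence as line
    densities, planar-polarity profiles and ratiometric (Vinculin over
    E-cadherin) load read-outs. Includes length-conditioned and per-cell
    (local) correlation statistics that remove the inverse-length confound,
    laser-ablation recoil and intensity analyses, and a synthetic-tissue
    generator that produces exactly force-balanced polygonal cell networks
    with known ground-truth tensions, rendered fluorescence stacks and
    simulated ablations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    EBImage,
    igraph,
    jsonlite,
    stats,
    utils,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
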