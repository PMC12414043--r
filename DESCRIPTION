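Package: aneuwall
Title: Haemodynamics of Thin-Walled Aneurysm Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking intraoperatively visible thin-walled regions of
    intracranial aneurysms to local haemodynamics. Provides CIELAB Delta E
    colour segmentation of intraoperative wall images, per-node wall shear
    stress metrics (time-averaged WSS, oscillatory shear index, relative
    residence time, WSS divergence, systolic WSS and pressure) computed from
    time-resolved surface shear fields on triangulated meshes, patch-based
    regional sampling of thin versus normal-appearing wall, and nested linear
    mixed-effects comparison of the two region types. A seeded synthetic-data
    module generates aneurysm meshes, pulsatile surface fields with known
    injected region effects, and intraoperative-style images with ground-truth
    masks, so the full pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    igraph,
    lme4,
    lmerTest,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
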