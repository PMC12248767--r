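Package: xenalign
Title: Automatic Keypoint Identification for Aligning H&E and Xenium
    DAPI Morphology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies matched cell nuclei between an H&E histology image
    and the DAPI-stained morphology image of a 10x Genomics Xenium run, and
    writes a keypoint alignment file that Xenium Explorer can import in place
    of manually placed landmarks. Candidate nuclei are scored by
    multi-directional PSNR between image patches, then filtered by Delaunay
    triangulation edge-consistency matching and by convex nucleus-polygon
    overlap. Includes a synthetic paired-scene generator so every stage is
    testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
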