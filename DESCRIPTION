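Package: panicler
Title: Multi-View Image-Based Phenotyping of Rice Panicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-destructive digital phenotyping of developing rice panicles
    from multi-view imaging sessions. Reads colored 3D point clouds produced
    by external multi-view-stereo reconstruction, segments the panicle from
    the constant chamber reference geometry (checkerboard walls, board, hook),
    scales and aligns clouds into a shared canonical frame, and voxelizes them
    on a common bounding cube to extract voxel-count and color-intensity
    traits including the red-to-green maturation ratio. Also implements the
    competing multi-view 2D pixel-count method with solidity, eccentricity
    and area region filtering, flatbed-scan seed morphometry via
    morphological opening, correlation and clustering statistics over trait
    tables, and seeded synthetic-data generators with ground truth so the
    whole pipeline is testable without real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    pracma,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
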