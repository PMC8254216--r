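Package: epiproj
Title: Local Z Projection and Deprojection Morphometrics for Curved Epithelia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Projects curved epithelial layers from 3D multi-channel image
    stacks onto a 2D plane using a locally extracted reference surface
    (height-map), and lifts 2D cell segmentations back onto that surface to
    obtain distortion-corrected 3D morphometrics per cell: apical area,
    perimeter, orientation, eccentricity, neighbour counts, apical-plane
    slope, Euler angles and local surface curvatures. Includes a
    ground-truthed synthetic epithelium generator (curved surfaces, Voronoi
    cell lattices, spurious cuticle and fat-body layers), RMSE-based
    evaluation of projections and height-maps against ground truth, a
    two-pass streaming mode for stacks larger than memory, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
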