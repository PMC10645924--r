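Package: carofem
Title: Patient-Specific Stress Analysis of Atherosclerotic Carotid Arteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for quantifying mechanical stress in atherosclerotic
    carotid arteries from segmented surface geometry. Generates seeded
    synthetic carotid bifurcation anatomies emulating CT-angiography
    segmentation output, reconstructs the vessel wall and fibrous plaque
    component by a contour-driven semi-automatic CAD procedure (convex-hull
    merging, B-spline contour smoothing, 30 percent outer-wall enlargement,
    narrowing removal, lofting and per-plane Boolean operations),
    tetrahedralizes the wall solid with plaque-local refinement, assigns
    material subsets by a minimum-distance-vector rule, solves the static
    linear-elastic problem under patient-specific differential lumen
    pressure, and post-processes per-element von Mises stresses into the
    VM99 statistic, cumulative volume-stress curves, plaque composition
    percentages, fibrous-cap thickness, signed surface distances and
    modulus sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
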