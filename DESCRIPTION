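Package: sketchkit
Title: Headless Toolkit for Medical Image Annotation, Drag-Based Proofreading
    and Iterative Annotation Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless library and command-line toolkit for medical image
    annotation pipelines: typed annotation objects (landmarks, bounding boxes,
    contours, curves, scribbles, label masks, surface meshes) anchored in the
    physical space of a NIfTI volume; a free-form-deformation (FFD) drag tool
    that corrects 2D contours and 3D surfaces from a single drag gesture via a
    6-per-axis control grid with cubic Bernstein tensor-product weights;
    surface reconstruction from sparse annotation (signed-distance
    interpolation of interleaved slice contours, thin-plate-spline fitting of
    open fissure-like surfaces) and thresholded voxel extraction inside a
    region of interest; a configuration-file plugin protocol that exchanges
    images, meshes and annotations with external programs through files on
    disk; and an annotation-by-iterative-learning loop (seed, train, predict,
    proofread, retrain) against a pluggable model contract, with a simulated
    proofreader for desk-scale experiments. A phantom generator provides
    seed-deterministic synthetic volumes, contours and surfaces with analytic
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
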