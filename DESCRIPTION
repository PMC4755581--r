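Package: vsmcseg
Title: Semi-Automatic 3D Segmentation and Morphometry of Vascular Smooth
    Muscle Cells in Confocal Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs individual vascular smooth muscle cells (VSMCs)
    from two-channel confocal z-stacks of cell clumps. A nucleus-seeded
    ray-fan "edge blocking" model retains first-intersection edge segments
    per cell, gaps are classified and filled by bilateral spline
    interpolation or Laplace-verified principal component analysis, and
    boundaries are propagated across slices by a stable-edge score. Stacked
    2D boundaries are reconstructed into 3D binary volumes and smoothed
    surface meshes, from which cell length, width, thickness, slenderness,
    in-plane angle and out-of-plane tilt angle are extracted. A virtual
    ellipsoid phantom (voxelized, optionally harmonically deformed)
    validates the covariance-PCA tilt-angle estimator, and a synthetic
    fusiform-cell stack generator makes the whole pipeline testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    Matrix,
    mclust,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'utils-geometry.R'
    'utils-image.R'
    'config.R'
    'phantom.R'
    'synthetic.R'
    'preprocess.R'
    'edgeBlocking.R'
    'edgeGrowing.R'
    'stableEdge.R'
    'reconstruction.R'
    'morphometry.R'
    'pipeline.R'
    'io.R'
    'vsmcseg-package.R'
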