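Package: srp3d
Title: Three-Dimensional Sorted Random Projection Texture Descriptors for
    Nuclear Chromatin Analysis
Version: 0.1.0
Authors@R:
    person("srp3d", "maintainers", email = "srp3d@example.org",
           role = c("aut", "cre"))
Description: Computes three-dimensional Sorted Random Projection (3D SRP)
    texture descriptors for volumetric fluorescence microscopy images of
    cell nuclei. Cubic patches of a DAPI volume are traversed by
    hyperplanes rasterized with a 3D Bresenham line algorithm; sorted
    intensity and difference patterns of each plane are compressed with
    fixed +1/-1 random-projection matrices and pooled into per-patch
    histogram descriptors. Includes bag-of-visual-words and Fisher-vector
    image encoding, an RBF-kernel support vector machine with grouped
    10-fold cross-validation for phenotype classification,
    heterochromatin-to-euchromatin intensity and aggregation ratios with
    rank-based group comparisons, a synthetic DAPI nucleus phantom
    generator, multi-page TIFF input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
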