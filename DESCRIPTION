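Package: tau3d
Title: Slope-Chain-Code Tortuosity for 3D Voxelized Objects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a tortuosity shape descriptor (tau3D) for binary
    voxel volumes. Cross-sections along the three grid axes are traced as
    inter-pixel crack contours, the stair-stepping artifact of
    voxelization is filtered by contour downsampling followed by a
    digital-straight-segment polygonal approximation, each filtered
    contour is encoded as a Slope Chain Code whose summed absolute
    normalized slope changes give the 2D tortuosity, and per-slice values
    are aggregated into a slice-count-normalized 3D measure. Includes
    deterministic synthetic shape generators (spheres, cubes, bumpy
    spheres) for validation, a morphological-closing smoothing
    experiment, and nonparametric two-group cohort statistics with a
    bundled Alzheimer's-disease brain-lobe tortuosity table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
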