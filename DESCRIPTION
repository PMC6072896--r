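Package: freewater
Title: Upper-Limit Free-Water Fraction Mapping from Single-Shell Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates a voxelwise upper limit on the free-water volume
    fraction from conventional single-shell diffusion tensor imaging. Fits
    the diffusion tensor by log-linear least squares, decomposes it into
    eigenvalues, and divides the third eigenvalue by the diffusivity of
    water at brain temperature (clamped to [0,1]) to bound the fraction of
    unrestricted water in each voxel. Includes standard DTI indices (FA,
    mean/axial/radial diffusivity), a synthetic two-compartment phantom
    generator with known ground truth, NIfTI-1 input/output with FSL-style
    gradient tables, region-of-interest statistics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
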