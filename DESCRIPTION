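Package: difftomo
Title: Differentiable Computed-Tomography Projectors and Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for computed-tomography simulation and
    reconstruction in which every operator exposes an analytic gradient, so
    reconstruction pipelines can be chained and optimised end to end.
    Provides ray-driven forward projectors and voxel-driven back projectors
    for parallel-, fan- and cone-beam geometries (cone beam via 3x4
    projection matrices on a circular orbit), Ram-Lak/ramp filtering with
    cosine and Parker short-scan redundancy weights, filtered backprojection
    and FDK reconstruction, analytic ellipse phantoms (including the 2D/3D
    Shepp-Logan head phantom) with a closed-form Radon-transform oracle,
    total-variation regularised iterative reconstruction by gradient
    descent, and gradient-based learning of the reconstruction filter.
    Volumes and sinograms are read and written as MetaImage (MHD/RAW);
    scan geometries as YAML; projection matrices as plain text.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
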