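Package: tracemap
Title: Reconstruction and Atlas Normalization of Serial-Section Tracer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts serial stacks of 2D histology section images into 3D
    volumes registered to a labeled reference template, and maps plotted
    neuron and injection-site coordinates through the composed transformations
    into template stereotaxic space. Provides mutual-information rigid and
    affine registration, demons-style deformable registration with
    landmark point-set constraints, atlas-based cortical-area assignment
    with nearest-structure fallback, Laplace-equation cortical thickness
    and normalized depth, a synthetic phantom generator with ground-truth
    transforms for validation, and accuracy-assessment statistics
    (injection-site discrepancies, per-area percentage agreement, and
    sparse-connection concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
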