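Package: MeshOverlap
Title: Mesh-Based Regional Comparison of 3D Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compares 3D segmentations of small anatomical structures
    (e.g. hippocampi) through triangulated surfaces rather than voxel
    resampling. Label volumes are converted to watertight meshes by a
    marching-cubes variant, global and regional Jaccard overlap indices
    and volumes are computed by counting points of a fine regular grid
    inside the surfaces, structures are partitioned into anterior,
    middle and posterior regions along their long axis, registration
    chains are checked with the full-circle consistency method, and
    volumes and transformed Jaccard indices are analysed with linear
    mixed models selected by backward AIC elimination. Synthetic phantom
    generators (analytic shapes, perturbed back-to-back pairs, factorial
    observation tables) make the whole pipeline testable without scan
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    lme4,
    lmerTest,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
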