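Package: odfpeaks
Title: Fiber Orientation Extraction from Diffusion ODFs by a PSO-Powell
    Hybrid Optimizer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Extracts all fiber orientations (local maxima) from diffusion
    MRI orientation distribution functions (ODFs) using a hybrid of a
    derandomized particle swarm optimizer and a modified Powell direction-set
    search. Includes multi-tensor HARDI phantom simulation with Rician noise
    and exact analytic ODFs, spherical-harmonic ODF reconstruction by q-ball
    imaging (QBI) and constant-solid-angle QBI, diffusion-tensor fits for
    fractional-anisotropy masking, an angular-deviation evaluation harness
    for crossing-fiber experiments, and NIfTI/bval/bvec input and output with
    a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
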