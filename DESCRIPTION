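Package: gmauth
Title: Identity Authentication from Normalized Gray-Matter Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-level matching of spatially normalized gray-matter (GM)
    probability volumes for biometric identity authentication. Implements the
    L1 (sum of absolute voxelwise differences) brain-matching distance with
    min-max normalization of matching scores to [0, 100], the full
    verification protocol (genuine/imposter pair enumeration for Same-Visit
    and Different-Visit experiments, FAR/FRR threshold sweeps, ROC curves,
    equal error rate), closed-set rank-1 identification against an enrolled
    gallery, isotropic Gaussian smoothing of GM maps, NIfTI-1 input/output,
    and a seeded synthetic GM phantom generator with subject/visit/scan
    variance structure for end-to-end evaluation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
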