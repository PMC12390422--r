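Package: marrowvar
Title: Bone Marrow Fat-Fraction Heterogeneity Analysis for Murine Myelofibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Longitudinal analysis of proton density fat fraction (PDFF) MRI
    of mouse tibia bone marrow in myelofibrosis. Segments the marrow region of
    interest into proximal, transition and distal zones from the axial mean
    PDFF trajectory, scores each image by the upper-percentile-trimmed voxel
    variance of distal PDFF values, and performs group-level inference
    (permutation tests, principal component analysis with a label-permutation
    separation p-value, per-mouse linear regression, quartile summaries, and
    disease/responder classification). Includes a synthetic tibia-phantom
    generator with calibrated disease courses so the full pipeline runs with
    no external imaging data, and bundles the published per-mouse variance
    table as a fixture.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
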