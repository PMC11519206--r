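Package: cbmaprep
Title: Data Preparation and Post Hoc Resampling for Coordinate-Based
    Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for preparing coordinate-based meta-analysis (CBMA)
    datasets and for generating the resampled inputs used in post hoc
    validation. Reads and writes Sleuth-compatible foci text files
    (with duplicate-experiment removal), enforces within-paper sample
    independence, filters foci by tissue masks on a Talairach 2 mm grid,
    selects experiments for meta-analytic connectivity modeling (MACM),
    generates leave-one-experiment-out and subset partitions, and computes
    dataset diagnostics (sample-size and publication-year histograms).
    An extension module computes modeled-activation and activation
    likelihood estimation (ALE) maps with a pluggable sample-size-dependent
    Gaussian kernel, and a voxel-wise robustness index aggregating
    thresholded significance maps across subsamples. A synthetic-data
    generator produces foci files and toy NIfTI masks for fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
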