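Package: cranioplan
Title: Quantitative Assessment of Neurosurgical Planning Accuracy on
    Patient-Specific 3D Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to score the accuracy of simulated neurosurgical planning
    drawings (tumor projection painting, linear and U-shaped incisions,
    craniotomy borders) against the orthographic silhouette of an underlying
    tumor on patient-specific head models. Provides a synthetic layered head
    phantom (scalp, skull, tumor) with label-volume voxelization and
    isosurface mesh extraction, a planar projection and region-overlap
    engine with rasterized reference semantics, the seven planning-accuracy
    metrics (percent tumor coverage, excess coverage, painted area, incision
    deviation from the tumor epicenter, U-incision and craniotomy scores,
    craniotomy margin deviation), a calibrated cohort simulator for paired
    pre/post assessment designs, and paired t / Wilcoxon signed-rank
    comparison with tidy summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
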