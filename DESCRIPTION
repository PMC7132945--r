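Package: dissectr
Title: Virtual Dissection and Tractometry of Commissural White Matter Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale pipeline for semiautomated virtual dissection of
    commissural white matter tracts from diffusion-weighted MRI:
    deterministic ROI-gated streamline tractography over a per-voxel peak
    orientation field, transverse segment extraction between sagittal cut
    planes, vertex-weighted FA/MD tractometry, and a complete
    structure-cognition statistics layer (bootstrap Pearson correlations,
    Bonferroni-Holm correction, Steiger tests for dependent correlations
    with Cohen's q, intracranial-volume adjustment of regional volumes,
    Spearman and outlier sensitivity analyses, and a default Bayes factor
    for a Pearson correlation). Ships a synthetic multi-bundle diffusion
    phantom generator with ground truth and a cohort simulator so the whole
    pipeline is testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    yaml,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
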