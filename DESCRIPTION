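Package: tractvlsm
Title: Voxel- and Tract-Based Lesion-Symptom Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating the location of cerebral small-vessel lesions
    to cognitive performance. Implements mass-univariate voxel-based
    lesion-symptom mapping (per-voxel two-sample t-tests of covariate-adjusted
    cognitive scores with Benjamini-Hochberg false-discovery-rate control and
    3D connected-component clustering), probabilistic white-matter-tract
    region-of-interest volumetry with a voxel-count tract-selection rule, and
    a hierarchical ladder of nested linear models quantifying strategic-location
    effects of lacunar and white-matter lesions over total lesion burden.
    Includes a fully synthetic lesion-cohort generator with known planted
    effects for parameter-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
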