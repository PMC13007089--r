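Package: peristab
Title: Peritumoral Mechanical Instability Mapping from MR Elastography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise mapping and topological analysis of mechanical
    instability at the tumor-brain interface from magnetic resonance
    elastography (MRE). Reads co-registered storage (G') and loss (G'')
    modulus volumes with tumor and brain masks, derives rim and peritumoral
    shell regions with an anisotropy-aware Euclidean distance transform,
    computes the rim-referenced instability index I(x), and summarizes its
    magnitude, radial persistence, and 2D skeleton topology per case.
    Includes a seeded synthetic phantom generator emulating compact,
    irregular, and branched peritumoral archetypes, group-average
    probability maps (with tumor-radius normalization), and a nonparametric
    comparison suite (Kruskal-Wallis, Mann-Whitney U, Benjamini-Hochberg
    FDR, Cliff's delta, Hodges-Lehmann shifts, case-resampling bootstrap).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    generics,
    pracma,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
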