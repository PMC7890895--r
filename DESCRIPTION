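Package: regevo
Title: Comparative Evolution of Tissue Regulomes from Histone-Mark Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies histone-mark ChIP-seq peaks (H3K4me3, H3K27ac,
    H3K4me1) into active promoters, active enhancers and primed enhancers,
    scores their tissue specificity within a species, and tracks their
    maintenance and signature switching across species through pairwise
    genome-alignment maps. Implements the recently-evolved/maintained
    partition of a regulome, linear evolutionary-rate regressions anchored
    by replicate-level zero points, outgroup-parsimony estimation of a
    promoter/enhancer transition matrix from species triads, and
    transposable-element (LINE L1/L2) relative-enrichment statistics.
    Ships a forward simulator of regulome evolution on a phylogeny with
    recorded ground truth, so the full pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    ape,
    withr,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
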