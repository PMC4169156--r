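Package: zfvar
Title: Missense Variants at DNA-Contacting Positions of C2H2 Zinc Finger Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects C2H2 zinc finger repeats and TGEKP-linked finger arrays in
    protein sequences, maps missense variants onto the recognition-helix position
    map (DNA-contacting positions -1, 2, 3, 6 versus non-contacting C2, -2, 1, 5),
    tests per-population genotype counts for Hardy-Weinberg deviation (chi-square
    and conditional exact test, heterozygote-excess statistic D), quantifies
    predicted binding-specificity change between reference and variant fingers as
    the summed Kullback-Leibler distance between position frequency matrices, and
    summarises common-variant depletion and deleteriousness predictions. Ships a
    synthetic-data generator with planted ground truth so the whole pipeline can
    be exercised and validated end to end without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
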