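Package: updtrio
Title: Uniparental Disomy Landscape Analysis from Trio Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises uniparental disomy (UPD) from jointly
    genotyped parent-offspring trios. Classifies every variant site into
    biparental, UPD-supportive and Mendelian-error categories, calls runs of
    homozygosity in the proband with a two-state hidden Markov model, clusters
    supportive variants into parent-of-origin UPD segments, types each segment
    as isodisomy or heterodisomy by its homozygosity overlay, localises the
    isodisomy/heterodisomy breakpoint to the informative-marker interval, and
    scans isodisomy segments for recessive alleles unmasked by UPD. Includes a
    meiotic nondisjunction / trisomy-rescue trio simulator that provides ground
    truth for every stage.
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
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
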