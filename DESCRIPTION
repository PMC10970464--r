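Package: polyssr
Title: Cross-Assembly Discovery of Polymorphic Microsatellite Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines perfect microsatellites (SSRs) in a reference genome
    assembly, filters SSR regions by structure and context, designs PCR
    primer pairs under nearest-neighbor melting-temperature constraints,
    screens amplicon segments for extra low-complexity sequence, amplifies
    every primer pair in silico in two or more related assemblies, and
    reports only markers amplified exactly once per assembly whose length
    variation is entirely attributable to SSR repeat-number differences.
    Includes a synthetic multi-assembly fixture generator with a planted
    truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    stats,
    parallel
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
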