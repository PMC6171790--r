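Package: irisdup
Title: Mapping a Tandem Duplication Behind Blue Eyes in Dogs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale re-implementation of the discovery chain used to map
    a 98.6-kb tandem duplication upstream of ALX4 associated with blue eyes
    and heterochromia in Siberian Huskies: mixed-model genome-wide association
    on a breed-structured cohort, tandem-duplication detection from scaled
    read depth and opposite-orientation discordant read pairs, SNP-array
    delta log R duplication genotyping, core-haplotype fine-mapping with
    penetrance and modifier analysis, and hard-filter variant triage. A
    synthetic cohort generator emulates the statistical structure of the
    study data so the whole pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    vcfR,
    Rsamtools,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
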