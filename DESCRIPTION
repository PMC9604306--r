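Package: gardenspot
Title: Permutation-Null Hotspot Assessment for Urban Biodiversity Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether a small focal area (such as an urban
    botanical garden) is a biodiversity hotspot relative to the city it sits
    in, using point-occurrence records from community-science platforms.
    Occurrence CSVs with Darwin-Core-style columns are read, validated,
    date-filtered and de-duplicated; species richness and Shannon diversity
    are computed with observation counts as the abundance proxy; a null
    distribution is built by repeatedly sampling city rectangles of the same
    dimensions as the garden, centred with replacement on observed
    coordinates; and the garden is scored as a percentile of that
    distribution, with an a-priori hotspot call above the 75th percentile.
    A seeded synthetic occurrence generator (log-normal species abundances,
    clustered observation effort, cross-platform duplicates, optional garden
    enrichment) supports calibration and power studies without any download.
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
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
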