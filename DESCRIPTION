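Package: rfscontrast
Title: Cohort Contrasts of Somatic Variants, Expression and Copy Number by
    Recurrence-Free Survival Group
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares groups of IDH1 wild-type glioblastoma defined by short,
    medium or long recurrence-free survival. Provides per-group mutational
    burden accounting, per-gene burden matrices with hypermutation flagging,
    group set algebra over mutated genes and variant keys (group-exclusive,
    universally shared and recurrent structures), 2x2 contingency tests on the
    resulting counts, differential-expression Venn partitioning across three
    groups, windowed log2-ratio copy-number contrasts with SD-banded segment
    calling and expression concordance, integrated per-gene reports, and a
    seeded synthetic-cohort generator with planted ground truth so the whole
    pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
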