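Package: meiorec
Title: Crossover and Noncrossover Calling and Classification from Yeast Tetrad Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of meiotic recombination from four-spore
    tetrad SNP genotypes. Calls gene-conversion tracts and crossover
    breakpoints from per-spore parental-origin calls, groups nearby tracts
    and breakpoints into recombination events, classifies events into the
    E1-E7 taxonomy (simple and discontinuous crossovers and noncrossovers,
    two-, three- and four-chromatid complex events, with E5A/E5B subtypes),
    quantifies tract discontinuity, and provides null-model randomizations
    (random noncrossover placement over a fixed crossover map; the 1:2:1
    no-chromatid-interference ratio for apparent double crossovers). A
    synthetic meiosis generator emulates a yeast-hybrid marker map with
    wild-type and mutant-like (mms4, sgs1, msh2) recombination signatures
    and emits ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph,
    vcfR,
    yaml,
    jsonlite
Config/testthat/edition: 3
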