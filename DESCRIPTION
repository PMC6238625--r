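Package: clockloops
Title: Feedback-Loop Analysis of a Five-Gene Circadian Clock Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a five-gene delay-differential-equation model of the
    mammalian circadian core clock (Bmal1, Dbp, Per2, Cry1, Rev-erb-alpha)
    to circadian expression profiles by particle swarm optimization seeded
    with a gradient-matching initialization ("vector field optimization"),
    then dissects each fitted model by systematically clamping genes and
    regulatory terms to constants to identify the negative feedback loops
    that are essential for self-sustained oscillation and the minimal loop
    sets ("rhythm-generating oscillators") that suffice for rhythmicity.
    Includes ensemble statistics across fits and tissues (loop frequencies,
    PCA/LDA parameter-space projections, Venn-style oscillator composition,
    rank-sum comparisons, circular phase statistics) and a synthetic-data
    generator emulating tissue-specific circadian transcript profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
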