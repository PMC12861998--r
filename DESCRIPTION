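Package: epigain
Title: Stochastic Simulation of Long-Term Genomic Selection with Epistasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-cycle genomic-selection breeding programs in
    self-pollinated crops to study how progeny size, number of crosses, budget
    constraints and additive-by-additive epistasis shape long-term genetic
    gain. Provides a map-based meiosis engine, founder and trait-architecture
    generators with heritability and epistatic-variance calibration, a
    two-kernel GBLUP fitted by Newton-Raphson REML with kinship projection
    onto unphenotyped individuals, the test-and-shelf recurrent selection
    scheme, and replicate-level comparison statistics (Welch ANOVA,
    omega-squared, Games-Howell).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
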