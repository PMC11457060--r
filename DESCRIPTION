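Package: strigaGS
Title: Genomic Prediction of Striga Resistance in Tropical Maize Testcrosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for genomic selection in maize breeding under artificial
    Striga hermonthica infestation. Derives resistance traits from plot
    records (area under the Striga number progress curve, damage ratings,
    grain yield from ear weight), fits single-site and across-site linear
    mixed models for alpha-lattice testcross trials by REML to obtain BLUEs,
    BLUPs, variance components and broad-sense heritability, builds a genomic
    relationship matrix from dominant presence/absence markers, fits a
    Bayesian reaction-norm genotype-by-environment model by Gibbs sampling to
    estimate genomic breeding values of tested and untested doubled-haploid
    lines, and evaluates prediction accuracy under the CV0, CV1 and CV2
    sparse-testing cross-validation schemes. A synthetic-data generator
    emulates multi-location alpha-lattice trials with user-set variance
    components so the whole analysis is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
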