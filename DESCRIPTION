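Package: songkin
Title: Kin Signatures, Individuality and Group Cues in Primate Song Phrases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether the acoustic structure of song phrases
    carries information about genetic relatedness, individual identity and
    group membership in singing primates. The package extracts temporal and
    frequency parameters from unit boundaries and fundamental-frequency
    contours of descending phrases, reduces them with principal components
    analysis under the Kaiser (eigenvalue > 1) criterion, builds normalized
    phrase- and individual-level Euclidean dissimilarity matrices, estimates
    pairwise relatedness from co-dominant microsatellite genotypes (four
    moment estimators and a dyadic maximum-likelihood estimator, with a
    simulation-based estimator comparison over dyads of known relatedness),
    and tests hypotheses with seeded matrix permutation (Mantel) tests,
    kin-category binary-matrix Mantel tests, and permuted discriminant
    function analysis with a test and a control factor. A synthetic-data
    module generates pedigrees, Mendelian microsatellite genotypes and phrase
    datasets with tunable individual, sex, heritable and group effects so the
    whole pipeline is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
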