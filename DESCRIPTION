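Package: karyofuse
Title: Null Models and Tests for Sex Chromosome-Autosome Fusions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Closed-form null probabilities for the three classes of
    chromosomal fusion (sex-autosome, autosome-autosome, sex-sex) as a
    function of karyotype and sex chromosome system, an exact multinomial
    tail test for an excess of sex chromosome-autosome fusions, and a
    clade-level pipeline that fits a continuous-time Markov model of
    karyotype evolution on a phylogeny, draws stochastic character maps,
    and compares the observed proportion of sex-autosome fusions against
    the time-weighted null expectation. Includes a synthetic-data module
    (Yule trees, forward simulation of karyotype histories) so the whole
    pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    yaml
Config/testthat/edition: 3
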