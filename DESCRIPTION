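Package: clearwing
Title: Convergence of Wing Transparency Under Predator Vision
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative analysis of mimetic convergence in wing
    transparency. Reads and smooths transmission spectra, computes
    receptor-noise-limited chromatic (dS) and achromatic (dL) contrasts
    under avian visual systems and natural illuminants, tests whether
    co-mimetic species are more similar than expected at random and given
    the phylogeny via permutation tests with phylogenetic residual
    correction, estimates phylogenetic signal for continuous, multistate
    and binary traits (Pagel's lambda, Blomberg's K, the delta statistic,
    Fritz and Purvis' D, phylogenetic ANOVA), and links transparency to
    wing micro- and nanostructure through phylogenetic generalised least
    squares with AICc all-subsets model selection. Includes a synthetic
    study generator (trees, mimicry rings, spectra, structural traits)
    with controllable convergence signal so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    withr,
    jsonlite
Config/testthat/edition: 3
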