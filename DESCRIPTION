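Package: cvqtl
Title: Mapping Quantitative Trait Loci for Stochastic Noise (CV) Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for treating the coefficient of variation (CV) of a
    replicated trait as a heritable phenotype in biparental recombinant
    inbred line (RIL) populations. Builds per-line CV phenotypes from
    replicated expression or metabolite matrices (per-trait, network,
    circadian phase-group, and genome-wide average CV) after quantile
    normalization; estimates broad-sense heritability of CV by a one-way
    random-effects variance decomposition; maps CV QTLs by composite
    interval mapping with Haley-Knott regression and permutation-derived
    genome-wide thresholds; detects trans-hotspots of co-localized QTLs
    against a positional permutation null; and provides direct
    variance-comparison tests (Levene's F, parental-expectation
    transgression models). Includes a synthetic-data generator that plants
    mean- and variance-QTLs into simulated selfed-RIL populations so the
    whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
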