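Package: emuflux
Title: Elementary Metabolite Unit Based 13C Metabolic Flux Analysis of
    Fermentative Yeast Central Carbon Metabolism
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Steady-state 13C metabolic flux analysis for Saccharomyces
    cerevisiae fermenting on a 40% [1-13C]glucose tracer. Provides an
    atom-mapped 60-reaction model of fermentative central carbon
    metabolism, an elementary metabolite unit (EMU) forward simulator of
    mass isotopomer distributions for proteinogenic amino-acid and
    glucose GC-MS fragments, the summed fractional labeling (SFL)
    statistic with natural-abundance correction, multi-start weighted
    least-squares flux estimation with convergent-solution averaging, a
    synthetic measurement generator for parameter-recovery studies, and
    NADPH redox accounting (pentose phosphate pathway versus acetate
    pathway contributions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
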