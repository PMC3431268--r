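# emuflux

Steady-state ¹³C metabolic flux analysis (MFA) of fermenting
*Saccharomyces cerevisiae*, for researchers studying how yeast reroutes
central carbon metabolism when cytosolic NADPH demand rises — e.g. a strain
expressing an engineered NADPH-dependent butanediol dehydrogenase that
reduces externally supplied acetoin (0–300 mM), forcing carbon into the
NADPH-producing oxidative pentose phosphate pathway (PPP) and the acetate
pathway (Ald6p).

The package provides the full pipeline:

* a 60-reaction atom-mapped model of fermentative central carbon metabolism
  (glycolysis, oxidative/non-oxidative PPP, glycerol branch, pyruvate and
  acetaldehyde nodes, mitochondrial OAA import, a TCA segment, amino-acid
  synthesis with explicit carbon maps, biomass drains, acetoin reduction);
* a forward simulator of GC-MS fragment mass isotopomer distributions by
  elementary metabolite unit (EMU) decomposition, for a 40% [1-¹³C]glucose
  tracer;
* the summed fractional labeling statistic of an *n*-carbon fragment,
  `SFL = 100 · (1·m1 + 2·m2 + … + n·mn) / (m0 + … + mn)`,
  with exact natural-abundance addition/correction for derivatization
  moieties (glucose pentaacetate, ECF and DMFDMA amino-acid derivatives);
* multi-start bounded least-squares flux estimation minimizing
  `Σ ((sim − obs)/σ)²` over 25 SFL + 22 flux measurements (47 items),
  reporting means ± SDs over the convergent solutions;
* a seeded synthetic-measurement generator and recovery harness built on
  the reported flux distributions of the four NADPH-demand conditions;
* NADPH bookkeeping (pathway production shares, PPP fold-changes).

## Worked example

Simulate labeling for the control condition, then recover the fluxes from
noisy synthetic measurements:

```r
library(emuflux)

model <- defaultCCMNetwork()
model
#> NetworkModel: 60 reactions, 48 metabolites ( 38 balanced )
#>   substrate: GLC.ext
#>   reversible: 9

flux0 <- referenceFluxes(0)           # control, per 100 mol glucose
tracer <- substrateLabeling()          # 40% [1-13C]glucose, 0.99 purity
head(simulateSFLs(model, flux0, tracer, defaultFragmentPanel()), 4)
#>    fragment       sfl
#> 1 glcpa_1_6 45.592000
#> 2 glcpa_2_6  5.350000
#> 3   ala_1_3 20.680697
#> 4   ala_2_3 18.069215

rep <- recoveryExperiment(condition = 0, sflSd = 0.3, fluxRelSd = 0.05,
                          nStarts = 20, seed = 1)
subset(rep$fit@fluxMeans, reaction %in% c("pgi", "zwf", "pdc", "ald6"))
#>    reaction       mean sd
#> 2       pgi  84.984795  0
#> 8       zwf  11.109132  0
#> 17      pdc 165.208578  0
#> 20     ald6  2.583527  0
```

The recovered glycolysis (PGI, true 84.7), oxidative PPP (ZWF, 11.4),
pyruvate decarboxylase (164.3) and acetaldehyde dehydrogenase (2.4) fluxes
sit within the measurement noise of their generating values; the `sd`
column is the dispersion of the convergent multi-start solutions (zero when
every start reaches the same optimum). NADPH bookkeeping at the highest
demand:

```r
nadphBalance(model, referenceFluxes(300))
#> RedoxReport (per 100 glucose)
#>   production:
#>     oxidativePPP     66.00  (92.2%)
#>     acetatePathway     5.60  (7.8%)
#>   ...
attr(pppFoldChange(referenceFluxes(300), referenceFluxes(0)), "rounded")
#> [1] 2.9
```

A thin command-line wrapper is shipped at `inst/scripts/emuflux.R`
(`simulate | generate | fit | recover | balance`, YAML config with flag
overrides).

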