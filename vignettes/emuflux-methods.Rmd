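---
title: "Methods: 13C flux analysis of fermenting yeast with emuflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 13C flux analysis of fermenting yeast with emuflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emuflux)
```

## The problem

During anaerobic growth on glucose, *Saccharomyces cerevisiae* regenerates
cytosolic NADPH mainly through the oxidative pentose phosphate pathway (PPP;
2 NADPH per glucose-6-phosphate oxidized by Zwf1p and Gnd1p) and through
acetate formation by the NADP⁺-dependent acetaldehyde dehydrogenase Ald6p.
When an artificial NADPH sink is installed — an engineered NADPH-dependent
butanediol dehydrogenase reducing externally supplied acetoin (0–300 mM) —
carbon is progressively rerouted into these two pathways. Steady-state
¹³C metabolic flux analysis (MFA) quantifies that rerouting: cells are grown
on a mixture of 40% [1-¹³C]glucose and unlabeled glucose, the isotope
patterns of proteinogenic amino acids and a glucose derivative are measured
by GC-MS, and the intracellular flux distribution is estimated by fitting an
atom-mapped network model to the labeling data plus measured uptake,
excretion and biomass-drain rates.

`emuflux` implements that pipeline end to end: the network model and its
flux algebra, a forward labeling simulator, the summed fractional labeling
(SFL) statistic, natural-abundance handling, a multi-start weighted
least-squares estimator with convergent-solution averaging, a synthetic-data
generator, and NADPH bookkeeping.

## The network model

`defaultCCMNetwork()` ships a 60-reaction atom-mapped model of fermentative
central carbon metabolism: glycolysis; the oxidative PPP (`zwf`, `gnd`, one
NADPH each) and non-oxidative PPP with two transketolase reactions and one
transaldolase carrying the standard C2/C3-unit transfers; the glycerol
branch; pyruvate decarboxylase and the acetaldehyde node (`adh`, `ald6`,
`acs`); pyruvate carboxylase with explicit mitochondrial import of
oxaloacetate; a TCA segment supporting glutamate, lysine and succinate
formation; amino-acid synthesis reactions with canonical carbon transitions
(e.g. valine and leucine through acetolactate, isoleucine through
threonine/2-ketobutyrate, aromatic amino acids from E4P + 2 PEP, lysine via
the α-aminoadipate route); twelve proteinogenic amino-acid drains plus
carbohydrate, lipid, nucleotide and C1 drains; and the external
acetoin-reduction reaction `bdh` carrying the imposed NADPH demand.

Carbon atoms are numbered from the carbonyl/carboxyl end (glucose C1 =
aldehyde). Atom maps are written as per-instance letter groups
(`abcde + fghij : abfghij + cde` for transketolase 1); the parser enforces
that every product carbon receives exactly one reactant carbon and every
reactant carbon is consumed once. Reactions draining into unmodeled sinks
(biomass) may leave their products unmapped; such reactions never produce a
balanced metabolite, so the labeling system is unaffected.

All fluxes are expressed in mol per 100 mol glucose consumed. The reported
pathway fluxes of the study system (ethanol ≈ 162, pyruvate decarboxylase
≈ 164 per 100 glucose) are only dimensionally consistent on this basis — two
pyruvate per glucose make a PDC flux above 100 natural — while the absolute
uptake (mmol/gDW/h) is kept as a scale annotation.

Reversible reactions (`pgi`, `tpi`, `gapdh`, `eno`, `rpe`, `rpi`, `tkl1`,
`tal`, `tkl2`) carry a bounded exchange parameter $x \in [0,1)$, mapped to
an exchange magnitude $x/(1-x) \times 100$ flux units. Exchange fluxes
affect labeling but not mass balances. With 25 SFL measurements the
exchanges are not structurally identifiable alongside 21 net degrees of
freedom, so they are fixed at documented defaults during fitting
(`defaultExchange()`: larger for near-equilibrium isomerases, moderate for
the transketolase/transaldolase system). This is a deliberate scope
decision; the estimator interface accepts any exchange configuration.

## Forward simulation (EMU)

The simulator uses elementary metabolite unit (EMU) decomposition: each
measured fragment is traced backwards through the atom maps, producing the
minimal set of (metabolite, carbon-subset) units whose mass isotopomer
distributions (MIDs) close the balance equations. Units of size $k$ depend
only on units of size $\le k$, so simulation is a cascade of small linear
solves, one per size block:

$$ A(v)\,X = B(v, Y) $$

with $A$ built from the direction fluxes (forward/backward flux of each
reaction), $X$ the unknown MIDs of one size, and $B$ accumulating substrate
inputs and convolutions of smaller units. The decomposition is computed once
per (model, panel) and cached; a single evaluation of the default 25-fragment
panel solves ~150 EMUs in 8 size blocks in a few milliseconds.

Correctness is established against an independent brute-force oracle in the
test suite: exhaustive positional-isotopomer enumeration with fixed-point
iteration on split/recombine networks with ≤ 6 carbons, agreeing with the
EMU path to < 10⁻⁸.

The tracer model is exact for glucose mixtures: the substrate EMU MIDs are
mixtures (labeled/unlabeled species) of products of per-position Bernoulli
distributions. Defaults: 40% [1-¹³C]glucose at 0.99 isotopic purity on C1,
with natural ¹³C abundance (0.0107) at every other position and throughout
the unlabeled fraction. Mixing linearity holds for the substrate itself, not
for downstream pools, and is asserted as such.

## SFL and natural abundance

For a fragment with $n$ backbone carbons and corrected mass fractions
$m_0 \dots m_n$,

$$ \mathrm{SFL} = 100 \times \frac{1\,m_1 + 2\,m_2 + \dots + n\,m_n}
{m_0 + m_1 + \dots + m_n} $$

in percent-labeled-carbon-equivalents (0 to $100\,n$). The measurement-side
convention: "corrected" means derivative-atom isotope contributions removed;
backbone natural ¹³C is not removed, and the simulator symmetrically
includes tracer-side natural abundance instead of adding backbone
correction. `addNaturalAbundance()` convolves a backbone MID with the exact
isotope mass-shift distribution of a derivatization moiety (any composition
of C/H/N/O/S); `correctNaturalAbundance()` inverts it by least squares on
the banded correction matrix, clipping and renormalizing noise-induced
negative entries (the clipped magnitude is reported). The pair round-trips
to < 10⁻⁸.

The packaged 25-fragment panel (glucose pentaacetate C1–C6 and C2–C6, plus
ECF and DMFDMA amino-acid fragments covering Ala, Val, Leu, Ile, Thr, Asp,
Glu, Ser, Gly, Phe, Tyr, Lys — a full-skeleton and a decarboxylated fragment
each, one fragment for glycine) is a reconstruction: the original fragment
list is not public, only its count. The moiety compositions are
representative of those derivative families. Because generation and fitting
use the same panel, panel composition affects realism, not internal
consistency; this is flagged wherever the panel is documented.

## Flux estimation

The estimator minimizes the weighted sum of squared residuals over all data
items (default 47: 25 SFLs + 22 fluxes),

$$ \mathrm{SSR}(\theta) = \sum_i
\left(\frac{y_i^{\mathrm{sim}}(\theta) - y_i^{\mathrm{obs}}}{\sigma_i}\right)^2, $$

where $\theta$ are 21 free net fluxes (glucose uptake is fixed at 100; the
dependent fluxes solve $S v = 0$ over the 38 balanced metabolites exactly).
The free set defaults to the measured reactions (15 biomass drains + 7
excreted metabolites) minus the CO₂ outflow, which the carbon balance makes
redundant.

Each start runs a staged local optimization:

1. **Linear stage.** The flux-measurement residuals are affine in $\theta$;
   that bounded linear least-squares problem is solved exactly by an
   active-set method (BVLS). This lands every start in the
   measurement-consistent region. A fraction of the random start (10%,
   clamped to ±5 measurement SDs per flux) is retained so different starts
   still probe different basins.
2. **Smoothed stage.** Bounded Levenberg–Marquardt on all residuals, with
   two regularizations that make the objective differentiable where fluxes
   change sign: the decomposition of net fluxes into direction fluxes uses a
   smooth positive part $(\sqrt{n^2+\varepsilon^2}+n)/2$
   ($\varepsilon = 0.1$), and irreversibility is enforced by a smooth
   penalty rather than a hard kink. SFL weights are additionally floored at
   an SD of 0.3 units during this pass, which prevents extremely tight
   weights from freezing the optimizer before it reaches the right basin.
3. **Sharp polish.** The same optimizer restarted on the exact
   (unsmoothed, true-weight) objective, so the reported optimum belongs to
   the exact model.

Multi-start estimation (`fitMultistart()`) draws the configured number of
starts uniformly within the bounds from a seeded generator (default bounds:
0 to 3×measured value + 10). The convergent subset keeps optimizer-converged
solutions with SSR within a factor $1+\delta$ ($\delta = 0.05$) of the best;
reported fluxes are the per-reaction means ± SDs over that subset, which by
linearity of the free-flux map satisfy the stoichiometric balance. The
"convergent solutions" rule is undefined in the source methodology; the
$\delta$ filter is the package's explicit, configurable formalization.
Historical practice used 100 starts; the recovery harness and tests default
to 20, which reaches the same convergent set on this problem at a fifth of
the cost.

Why the staging matters: the flux measurements nearly determine the flux
vector, but internal splits (glycolysis vs. PPP) amplify measurement noise
~20-fold, so the measurement-only solution can place the oxidative PPP flux
near or below zero. The labeling data then carry essentially all the
information about the split — exactly the point of ¹³C MFA — and the
smoothed stage lets the optimizer cross the irreversibility boundary into
the labeling-consistent basin instead of stalling on it.

## Reference flux distributions and their completion

`referenceFluxes(acetoin)` returns the study's reported flux distribution
for 0, 100, 200 or 300 mM acetoin, completed to a fully balanced 60-flux
vector. The reported table pins 13 pathway fluxes; the completion solves the
rest from the balances with these documented choices:

* The "glycolysis" entry is the PGI net flux — the only reading under which
  the G6P node closes against the reported PPP and carbohydrate values.
* The "transketolase" entry is the summed flux of both transketolase
  reactions, split so the S7P/E4P balances close; reading it as TKL1 alone
  forces negative pentose drains.
* Anabolic drains (not reported) use fixed control-condition values
  (e.g. Ala 0.50, Glu-family from the OAA-import/succinate gap), scaled
  across conditions by the reported carbohydrate drain as a growth proxy.
* The reported table is not exactly node-consistent at this granularity:
  the G6P node residual (up to 1.6 per 100 glucose) is absorbed into the
  carbohydrate drain, the acetate-node residual into acetate excretion, and
  a systematic triose-node shortfall (~7–13 per 100 glucose) into the
  glycerol branch (floored at 1.0; only the 200 mM column reaches the floor,
  where the small remainder lowers PDC). The fluxes central to the study's
  conclusions — glycolysis, oxidative PPP, PDC, ALD6 — are preserved
  exactly, so recovery experiments are measured against the reported values.
* The acetoin-reduction flux `bdh` (pure NADPH sink, no carbon coupling) is
  closed from the redox side: production (2×PPP + ALD6) minus the
  growth-scaled control-condition production.

## Synthetic data and the recovery harness

`generateDataset()` adds iid Gaussian noise to the forward-simulated SFLs
(truncated to each fragment's physical range) and to the 22 measured fluxes
(relative noise with an absolute SD floor of 0.1 so near-zero fluxes keep
positive weights; SFL SDs are floored at 0.01). Defaults — noise 0.3 SFL
units and 5% on fluxes — are the package's stand-in for the unpublished
measurement precisions, chosen once as typical GC-MS and rate-measurement
performance. Zero-noise datasets equal the forward simulation exactly and
are used for the structural-identifiability invariant: all four condition
presets are recovered with SSR ≈ 0 and free-flux errors < 1%.

`recoveryExperiment()` chains generation, fitting and comparison, and is the
package's acceptance harness. What passing recovery shows: the estimator
recovers the generating fluxes under the assumed noise model and panel. What
it does not show: robustness to model misspecification (wrong atom maps,
unmodeled pathways), non-Gaussian measurement error, or the true fragment
panel of any particular instrument.

## Redox accounting

`nadphBalance()` sums cofactor-ledger-weighted net fluxes: production from
the oxidative PPP (2 per G6P) and Ald6p; consumption from anabolic ledger
entries and the acetoin sink. Shares are percent of production and sum
to 100. `pppFoldChange()` reports the PPP flux ratio between conditions;
from the reported fluxes the factors are 1.6 (100 mM) and 2.9 (300 mM),
while the 200 mM ratio computes to 26/11.4 = 2.3 against a reported 2.4 —
the discrepancy is flagged and the 200 mM factor is excluded from
validation. The historical 80%/20% PPP/acetate split of NADPH supply derives
from a separate dynamic model with anabolic netting this package does not
reconstruct, and is deliberately not a validation target.

## Numerical choices and limitations

* Problem sizes: recovery runs use 20 starts on the 47-item problem
  (~1 minute each); property suites use 2-start zero-noise fits and ≤6-carbon
  oracle networks.
* Linear solves are dense LU per EMU size block; a zero-production pool
  raises a named error (`emufluxSingularEMU`) naming the pool. During
  optimization a 10⁻⁶ direction-flux floor keeps iterates defined.
* Succinate is treated as an ordered molecule (no symmetry scrambling); no
  measured fragment derives from it, so labeling predictions are unaffected.
* Degenerate inputs: all-zero MIDs, unreachable fragments, infeasible
  completions, non-basis free sets and ill-conditioned correction matrices
  raise classed errors rather than propagating NaNs.
* Multi-start SDs understate uncertainty when all starts converge to one
  optimum (the usual case here); they are the dispersion of the convergent
  set, not confidence intervals. Profile-likelihood intervals are out of
  scope.
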