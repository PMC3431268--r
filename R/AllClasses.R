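#' @import methods
#' @importFrom stats rnorm runif setNames sd
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' NetworkModel: an atom-mapped metabolic network
#'
#' Holds the metabolite table (name, carbon count, role), the reaction list
#' (stoichiometry expanded into per-molecule instances, carbon atom maps,
#' reversibility, compartment, cofactor ledger) and the designated substrate.
#' Objects are created by [loadNetwork()] or [defaultCCMNetwork()]; the
#' validity method enforces unique reaction ids, per-reaction carbon-map
#' bijections, carbon conservation among mapped species, and that every
#' balanced metabolite takes part in at least two reactions.
#'
#' @slot metabolites data.frame with columns `name`, `carbons`, `role`
#'   (`"substrate"`, `"balanced"` or `"external"`).
#' @slot reactions named list; each element has `id`, `reactants`, `products`
#'   (character vectors, one entry per molecule instance), `pmap` (per product
#'   instance, integer matrix with rows `src_inst`, `src_pos`, or `NULL` for
#'   an unmapped external sink), `reversible`, `compartment`, `cofactors`
#'   (named numeric, production per unit net flux).
#' @slot substrate name of the single substrate-uptake metabolite.
#' @export
setClass("NetworkModel",
  representation(metabolites = "data.frame", reactions = "list",
                 substrate = "character"))

#' FluxVector: net and exchange fluxes of a NetworkModel
#'
#' Net fluxes are in mol per 100 mol glucose consumed. Exchange fluxes of
#' reversible reactions are stored as the bounded parameter x in [0, 1);
#' the unbounded exchange magnitude is x / (1 - x) * scale (see
#' [exchangeMagnitude()]).
#'
#' @slot net named numeric, one entry per reaction id.
#' @slot exchange named numeric in [0, 1), one entry per reversible reaction.
#' @slot exchangeScale numeric scalar mapping the bounded parameter to flux
#'   units (default 100, the glucose-uptake basis).
#' @export
setClass("FluxVector",
  representation(net = "numeric", exchange = "numeric",
                 exchangeScale = "numeric"),
  prototype(exchange = numeric(0), exchangeScale = 100))

#' SubstrateLabeling: tracer specification for the glucose feed
#'
#' @slot fraction fraction of position-labeled (or uniformly labeled) glucose.
#' @slot purity isotopic purity of the labeled position(s).
#' @slot position labeled carbon position (1 for [1-13C]glucose).
#' @slot remainder `"natural"` (unlabeled glucose carries natural 13C) or
#'   `"pure12C"`.
#' @slot natural13C natural 13C abundance per carbon.
#' @slot mode `"positional"` or `"uniform"` (utility mode: every carbon of the
#'   labeled species is 13C at `purity`).
#' @export
setClass("SubstrateLabeling",
  representation(fraction = "numeric", purity = "numeric",
                 position = "integer", remainder = "character",
                 natural13C = "numeric", mode = "character"))

#' FreeFluxParam: null-space parameterization of the flux balance
#'
#' Encodes the split of the net-flux vector into fixed (equality-constrained),
#' free, and dependent reactions, with the dependent block solved from
#' S v = 0 over the balanced metabolites.
#'
#' @slot free character, ids of the free fluxes (in parameter order).
#' @slot fixed named numeric, equality constraints (e.g. `c(glk = 100)`).
#' @slot dep character, ids of the dependent reactions.
#' @slot qrDep QR factorization of the dependent stoichiometric block.
#' @slot Sknown matrix mapping (fixed, free) values into the dependent
#'   right-hand side.
#' @slot reactionIds full reaction id ordering of the parent model.
#' @export
setClass("FreeFluxParam",
  representation(free = "character", fixed = "numeric", dep = "character",
                 qrDep = "ANY", Sknown = "matrix", reactionIds = "character"))

#' FitProblem: measurements plus model, tracer and optimizer settings
#'
#' @slot model a [NetworkModel-class].
#' @slot tracer a [SubstrateLabeling-class].
#' @slot panel fragment panel data.frame (see [loadFragmentPanel()]).
#' @slot sfl data.frame `fragment`, `value`, `sd` of SFL measurements.
#' @slot fluxes data.frame `reaction`, `value`, `sd` of net-flux measurements.
#' @slot param a [FreeFluxParam-class].
#' @slot exchange named numeric, fixed exchange parameters in [0, 1).
#' @slot settings list: `nStarts`, `seed`, `delta`, `maxiter`, bounds.
#' @slot cache environment holding the compiled EMU system.
#' @export
setClass("FitProblem",
  representation(model = "NetworkModel", tracer = "SubstrateLabeling",
                 panel = "data.frame", sfl = "data.frame",
                 fluxes = "data.frame", param = "FreeFluxParam",
                 exchange = "numeric", settings = "list",
                 cache = "environment"))

#' FitResult: multi-start estimation result
#'
#' @slot fluxMeans data.frame `reaction`, `mean`, `sd` over the convergent set.
#' @slot starts data.frame per start: `start`, `ssr`, `converged`, `inSubset`.
#' @slot nConvergent number of solutions in the convergent subset.
#' @slot best the best-fit [FluxVector-class].
#' @slot solutions list of per-start free-flux vectors.
#' @slot residuals data.frame of weighted residuals at the best fit.
#' @slot settings list (seed, delta, nStarts as used).
#' @export
setClass("FitResult",
  representation(fluxMeans = "data.frame", starts = "data.frame",
                 nConvergent = "integer", best = "FluxVector",
                 solutions = "list", residuals = "data.frame",
                 settings = "list"))

#' SyntheticDataset: generated SFL and flux measurement tables
#'
#' @slot sfl data.frame `fragment`, `value`, `sd`.
#' @slot fluxes data.frame `reaction`, `value`, `sd`.
#' @slot provenance list: true fluxes, seed, noise settings, condition.
#' @export
setClass("SyntheticDataset",
  representation(sfl = "data.frame", fluxes = "data.frame",
                 provenance = "list"))

#' RedoxReport: NADPH production/consumption bookkeeping for a flux vector
#'
#' @slot production named numeric, NADPH produced per pathway/reaction.
#' @slot consumption named numeric, NADPH consumed (positive numbers).
#' @slot shares named numeric, percent of total production (sums to 100).
#' @slot net numeric, production minus consumption.
#' @export
setClass("RedoxReport",
  representation(production = "numeric", consumption = "numeric",
                 shares = "numeric", net = "numeric"))

.fmtNum <- function(x) formatC(x, format = "fg", digits = 4)

setMethod("show", "NetworkModel", function(object) {
  nb <- sum(object@metabolites$role == "balanced")
  cat("NetworkModel:", length(object@reactions), "reactions,",
      nrow(object@metabolites), "metabolites (", nb, "balanced )\n")
  cat("  substrate:", object@substrate, "\n")
  cat("  reversible:",
      sum(vapply(object@reactions, `[[`, TRUE, "reversible")), "\n")
})

setMethod("show", "FluxVector", function(object) {
  cat("FluxVector:", length(object@net), "net fluxes,",
      length(object@exchange), "exchange parameters\n")
  hd <- utils::head(object@net, 8)
  cat(paste0("  ", names(hd), " = ", .fmtNum(hd), collapse = "\n"), "\n")
  if (length(object@net) > 8) cat("  ...\n")
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult:", nrow(object@starts), "starts,",
      object@nConvergent, "convergent; min SSR =",
      .fmtNum(min(object@starts$ssr[object@starts$converged], Inf)), "\n")
})

setMethod("show", "RedoxReport", function(object) {
  cat("RedoxReport (per 100 glucose)\n  production:\n")
  for (n in names(object@production))
    cat(sprintf("    %-12s %8.2f  (%.1f%%)\n", n, object@production[[n]],
                object@shares[[n]]))
  cat("  consumption:\n")
  for (n in names(object@consumption))
    cat(sprintf("    %-12s %8.2f\n", n, object@consumption[[n]]))
  cat(sprintf("  net balance: %8.2f\n", object@net))
})
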