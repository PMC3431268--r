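# NADPH bookkeeping: pathway production, consumption, shares and
# fold-changes across NADPH-demand conditions.

#' NADPH balance of a flux vector
#'
#' Sums the cofactor-ledger-weighted net fluxes. Production is grouped into
#' the oxidative pentose phosphate pathway (glucose-6-phosphate and
#' 6-phosphogluconate dehydrogenases, 2 NADPH per G6P entering) and the
#' acetate pathway (NADP+-dependent acetaldehyde dehydrogenase);
#' consumption into anabolic drains and the acetoin-reduction sink
#' (engineered NADPH-dependent butanediol dehydrogenase). Shares are
#' percent of total production and sum to 100.
#'
#' @param model a [NetworkModel-class] whose reactions carry an `nadph`
#'   cofactor ledger.
#' @param flux a [FluxVector-class] or named numeric of net fluxes.
#' @return a [RedoxReport-class].
#' @export
nadphBalance <- function(model, flux) {
  v <- if (is(flux, "FluxVector")) flux@net else flux
  coef <- vapply(model@reactions, function(r) {
    cf <- r$cofactors
    if (length(cf) && "nadph" %in% names(cf)) cf[["nadph"]] else 0
  }, 0)
  if (all(coef == 0))
    .netError("emufluxNoLedger",
              "model carries no NADPH cofactor ledger entries")
  ids <- names(model@reactions)
  amt <- coef * v[ids]
  prodIds <- ids[coef > 0]
  consIds <- ids[coef < 0]
  production <- c(
    oxidativePPP = sum(amt[intersect(prodIds, c("zwf", "gnd"))]),
    acetatePathway = sum(amt[intersect(prodIds, "ald6")]))
  other <- setdiff(prodIds, c("zwf", "gnd", "ald6"))
  if (length(other)) production <- c(production, setNames(amt[other], other))
  consumption <- c(
    anabolism = -sum(amt[setdiff(consIds, "bdh")]),
    acetoinReduction = -sum(amt[intersect(consIds, "bdh")]))
  tot <- sum(production)
  shares <- if (tot > 0) 100 * production / tot else production * 0
  new("RedoxReport", production = production, consumption = consumption,
      shares = shares, net = tot - sum(consumption))
}

#' Pentose phosphate pathway flux fold-change between two conditions
#'
#' Ratio of the oxidative PPP net flux in a condition over the control.
#' Invariant to common rescaling of both vectors. The raw ratio is returned
#' with the 1-decimal rounded value in the `"rounded"` attribute.
#'
#' @param fluxCondition,fluxControl [FluxVector-class] objects, named numeric
#'   vectors containing `reaction`, or plain scalars (PPP fluxes).
#' @param reaction reaction id measuring the PPP flux (default `"zwf"`).
#' @return scalar ratio with attribute `"rounded"`.
#' @export
pppFoldChange <- function(fluxCondition, fluxControl, reaction = "zwf") {
  pick <- function(x) {
    if (is(x, "FluxVector")) x@net[[reaction]]
    else if (length(x) > 1 || !is.null(names(x))) x[[reaction]]
    else x
  }
  a <- pick(fluxCondition); b <- pick(fluxControl)
  if (!is.finite(b) || b <= 0)
    .netError("emufluxZeroControlFlux",
              "control PPP flux must be positive for a fold-change")
  r <- a / b
  attr(r, "rounded") <- round(r, 1)
  r
}
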