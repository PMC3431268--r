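# Substrate labeling (tracer) specification and substrate-side MIDs.

#' Specify the glucose tracer mixture
#'
#' The default models the study condition: 40% [1-13C]glucose (99% isotopic
#' purity at C1, natural 13C elsewhere on the labeled molecule) mixed with
#' unlabeled glucose carrying natural 13C abundance at every carbon.
#'
#' @param fraction fraction of labeled glucose in [0, 1].
#' @param purity 13C purity of the labeled position(s).
#' @param position labeled carbon (1 = aldehyde carbon of glucose).
#' @param remainder `"natural"` or `"pure12C"`: isotope content of unlabeled
#'   material (and of the non-labeled positions of the labeled species).
#' @param natural13C natural 13C abundance per carbon.
#' @param mode `"positional"` (default) or `"uniform"` (utility mode: all
#'   carbons of the labeled species carry `purity` 13C).
#' @return a [SubstrateLabeling-class].
#' @export
substrateLabeling <- function(fraction = 0.4, purity = 0.99,
                              position = 1L, remainder = c("natural",
                                                           "pure12C"),
                              natural13C = 0.0107,
                              mode = c("positional", "uniform")) {
  remainder <- match.arg(remainder)
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction <= 1, purity >= 0, purity <= 1)
  new("SubstrateLabeling", fraction = fraction, purity = purity,
      position = as.integer(position), remainder = remainder,
      natural13C = natural13C, mode = mode)
}

# Per-species per-position 13C probabilities; returns list of
# list(weight, p13 vector of length nCarbons)
.tracerSpecies <- function(tracer, nCarbons) {
  base <- if (tracer@remainder == "natural") tracer@natural13C else 0
  unl <- rep(base, nCarbons)
  lab <- rep(base, nCarbons)
  if (tracer@mode == "uniform") {
    lab[] <- tracer@purity
  } else {
    if (tracer@position <= nCarbons) lab[tracer@position] <- tracer@purity
  }
  list(list(weight = 1 - tracer@fraction, p13 = unl),
       list(weight = tracer@fraction, p13 = lab))
}

# MID of a substrate EMU covering `positions` (1-based carbon indices).
# Exact mixture of products of independent Bernoulli positions.
substrateMID <- function(tracer, positions, nCarbons) {
  sp <- .tracerSpecies(tracer, nCarbons)
  n <- length(positions)
  mid <- numeric(n + 1)
  for (s in sp) {
    if (s$weight == 0) next
    m <- 1
    for (p in s$p13[positions]) m <- convolve(m, rev(c(1 - p, p)),
                                              type = "open")
    mid <- mid + s$weight * m
  }
  mid
}
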