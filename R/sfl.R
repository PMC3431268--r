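# Summed fractional labeling (SFL) and natural-abundance handling for
# GC-MS fragment mass isotopomer distributions.

.isotopes <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425)
)

#' Check a mass isotopomer distribution
#'
#' A valid MID has entries >= -1e-12 and sums to 1 within 1e-9.
#'
#' @param mid numeric vector m0..mn.
#' @return TRUE invisibly; otherwise an error.
#' @export
checkMID <- function(mid) {
  if (any(mid < -1e-12))
    stop("MID has negative entries beyond tolerance")
  if (abs(sum(mid) - 1) > 1e-9)
    stop("MID does not sum to 1 within 1e-9")
  invisible(TRUE)
}

#' Summed fractional labeling of a fragment MID
#'
#' SFL = 100 * (1 m1 + 2 m2 + ... + n mn) / (m0 + m1 + ... + mn), in units of
#' percent-labeled-carbon-equivalents (range 0 to 100 n for an n-carbon
#' fragment).
#'
#' @param mid numeric MID vector m0..mn.
#' @return scalar SFL value.
#' @export
sfl <- function(mid) {
  tot <- sum(mid)
  if (tot <= 0) .netError("emufluxZeroMID", "all-zero MID has no SFL")
  100 * sum((seq_along(mid) - 1L) * mid) / tot
}

# elemental composition "C10H14O9" -> named integer vector
.parseFormula <- function(formula) {
  if (is.na(formula) || formula == "" || formula == "-") return(integer(0))
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(n == "", 1L, as.integer(n))
  setNames(as.integer(n), el)
}

#' Isotope mass-shift distribution of a derivatization moiety
#'
#' Convolves the natural isotope distributions of every atom in the given
#' elemental composition, truncating the negligible tail.
#'
#' @param formula elemental composition string, e.g. `"C10H14O9"`; empty or
#'   `"-"` gives the identity distribution.
#' @param tol tail truncation tolerance.
#' @return numeric vector of mass-shift probabilities (shift 0, 1, 2, ...).
#' @export
moietyDistribution <- function(formula, tol = 1e-12) {
  comp <- .parseFormula(formula)
  d <- 1
  for (el in names(comp)) {
    iso <- .isotopes[[el]]
    if (is.null(iso))
      stop("no isotope data for element ", el)
    for (i in seq_len(comp[[el]])) {
      d <- .conv(d, iso)
      cum <- cumsum(d)
      keep <- max(which(1 - cum > tol), 1L) + 1L
      d <- d[seq_len(min(keep, length(d)))]
    }
  }
  d / sum(d)
}

#' Add derivative-atom natural abundance to a backbone MID
#'
#' Forward model of the GC-MS measurement: convolves the carbon-backbone MID
#' with the isotope mass-shift distribution of the derivatization moiety.
#'
#' @param mid backbone MID.
#' @param moiety elemental composition string or a precomputed distribution.
#' @return raw (measured-scale) MID; longer than the input when the moiety
#'   can shift mass.
#' @export
addNaturalAbundance <- function(mid, moiety) {
  d <- if (is.character(moiety)) moietyDistribution(moiety) else moiety
  out <- .conv(mid, d)
  out / sum(out)
}

#' Correct a raw MID for derivative-atom natural abundance
#'
#' Inverts [addNaturalAbundance()] by least squares on the banded correction
#' matrix. Negative entries arising from measurement noise are clipped at
#' zero and the result renormalized; the clipped magnitude is reported in the
#' `"clipped"` attribute.
#'
#' @param raw raw MID (length n_backbone + moiety shifts, or just
#'   n_backbone + 1).
#' @param moiety elemental composition string or precomputed distribution.
#' @param n number of backbone carbons of the corrected MID (default: as many
#'   as the raw vector supports, i.e. `length(raw) - 1`).
#' @return corrected MID of length `n + 1` with attribute `"clipped"`.
#' @export
correctNaturalAbundance <- function(raw, moiety, n = length(raw) - 1L) {
  d <- if (is.character(moiety)) moietyDistribution(moiety) else moiety
  nr <- length(raw)
  C <- matrix(0, nr, n + 1L)
  for (j in seq_len(n + 1L)) {
    lo <- j; hi <- min(nr, j + length(d) - 1L)
    if (lo <= hi) C[lo:hi, j] <- d[seq_len(hi - lo + 1L)]
  }
  if (kappa(C) > 1e8)
    .netError("emufluxIllConditioned",
              "natural-abundance correction matrix is ill-conditioned")
  x <- qr.coef(qr(C), raw)
  clipped <- sum(pmin(x, 0))
  x <- pmax(x, 0)
  x <- x / sum(x)
  attr(x, "clipped") <- abs(clipped)
  x
}

#' Load a GC-MS fragment panel
#'
#' @param path TSV file with columns `fragment`, `metabolite`, `positions`
#'   (comma-separated 1-based carbons), `moiety`, `family`.
#' @return data.frame.
#' @export
loadFragmentPanel <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("fragment", "metabolite", "positions", "moiety", "family")
  if (!all(need %in% names(df)))
    stop("fragment panel must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$fragment)) stop("duplicate fragment ids in panel")
  df
}

#' The packaged default 25-fragment panel
#'
#' One glucose derivative (glucose pentaacetate) plus ECF and DMFDMA
#' amino-acid derivative fragments covering alanine, valine, leucine,
#' isoleucine, threonine, aspartate, glutamate, serine, glycine,
#' phenylalanine, tyrosine and lysine. The composition is a documented
#' package default: it reconstructs a typical panel for this tracer and
#' derivatization chemistry.
#'
#' @return data.frame with 25 rows.
#' @export
defaultFragmentPanel <- function() {
  loadFragmentPanel(system.file("extdata", "fragment_panel.tsv",
                                package = "emuflux", mustWork = TRUE))
}

#' Simulate SFL values for a fragment panel
#'
#' Convenience wrapper: [simulateMIDs()] followed by [sfl()] per fragment.
#'
#' @inheritParams simulateMIDs
#' @param panel fragment panel data.frame.
#' @return data.frame `fragment`, `sfl`.
#' @export
simulateSFLs <- function(model, flux, tracer, panel, system = NULL,
                         fluxFloor = 0, smoothEps = 0) {
  mids <- simulateMIDs(model, flux, tracer, panel, system = system,
                       fluxFloor = fluxFloor, smoothEps = smoothEps)
  data.frame(fragment = names(mids),
             sfl = vapply(mids, sfl, 0), row.names = NULL)
}
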