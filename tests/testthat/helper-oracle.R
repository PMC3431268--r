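# Independent brute-force oracle: exhaustive positional-isotopomer
# enumeration at steady state, solved by fixed-point iteration. Only the
# parsed atom maps are shared with the package; the flux handling,
# propagation and marginalization are implemented from scratch.

# per-metabolite isotopomer distributions; state index = bitmask + 1,
# bit (k-1) set <=> carbon k is 13C
bruteForceState <- function(model, tracer) {
  mets <- model@metabolites
  state <- list()
  for (i in seq_len(nrow(mets))) {
    n <- mets$carbons[i]
    if (mets$role[i] == "substrate") {
      p <- numeric(2^n)
      base <- if (tracer@remainder == "natural") tracer@natural13C else 0
      for (mask in 0:(2^n - 1)) {
        prUn <- 1; prLab <- 1
        for (k in seq_len(n)) {
          bit <- bitwAnd(bitwShiftR(mask, k - 1L), 1L) == 1L
          pu <- base
          pl <- if (tracer@mode == "uniform" || k == tracer@position)
            tracer@purity else base
          prUn <- prUn * if (bit) pu else 1 - pu
          prLab <- prLab * if (bit) pl else 1 - pl
        }
        p[mask + 1] <- (1 - tracer@fraction) * prUn + tracer@fraction * prLab
      }
      state[[mets$name[i]]] <- p
    } else if (mets$role[i] == "balanced") {
      p <- numeric(max(2^n, 1)); p[1] <- 1
      state[[mets$name[i]]] <- p
    }
  }
  state
}

# one direction of one reaction: production distributions for each product
bruteForceDirections <- function(model, flux) {
  dirs <- list()
  exch <- emuflux::exchangeMagnitude(flux)
  for (r in model@reactions) {
    if (is.null(r$pmap)) next
    e <- if (r$id %in% names(exch)) exch[[r$id]] else 0
    n <- flux@net[[r$id]]
    fw <- max(n, 0) + e
    bw <- if (r$reversible) max(-n, 0) + e else 0
    if (fw > 0)
      dirs[[length(dirs) + 1]] <- list(v = fw, reactants = r$reactants,
                                       products = r$products, pmap = r$pmap)
    if (bw > 0) {
      # invert the map for the backward direction
      bmap <- lapply(seq_along(r$reactants), function(i) {
        cols <- list()
        for (j in seq_along(r$pmap)) {
          m <- r$pmap[[j]]
          for (k in seq_len(ncol(m)))
            if (m["src_inst", k] == i)
              cols[[m["src_pos", k]]] <- c(j, k)
        }
        out <- matrix(0L, 2, length(cols),
                      dimnames = list(c("src_inst", "src_pos"), NULL))
        for (q in seq_along(cols)) out[, q] <- cols[[q]]
        out
      })
      dirs[[length(dirs) + 1]] <- list(v = bw, reactants = r$products,
                                       products = r$reactants, pmap = bmap)
    }
  }
  dirs
}

bruteForceIterate <- function(model, flux, tracer, tol = 1e-13,
                              maxIter = 20000) {
  state <- bruteForceState(model, tracer)
  dirs <- bruteForceDirections(model, flux)
  bal <- model@metabolites$name[model@metabolites$role == "balanced"]
  nc <- setNames(model@metabolites$carbons, model@metabolites$name)
  for (it in seq_len(maxIter)) {
    maxDelta <- 0
    for (met in bal) {
      prodDist <- numeric(2^nc[[met]])
      totFlux <- 0
      for (d in dirs) {
        hits <- which(d$products == met)
        for (j in hits) {
          totFlux <- totFlux + d$v
          # joint enumeration over reactant instances
          rs <- d$reactants
          sizes <- vapply(rs, function(m) 2^nc[[m]], 0)
          idx <- rep(1L, length(rs))
          contrib <- numeric(length(prodDist))
          repeat {
            pr <- d$v
            for (i in seq_along(rs)) pr <- pr * state[[rs[i]]][idx[i]]
            if (pr > 0) {
              m <- d$pmap[[j]]
              mask <- 0L
              for (k in seq_len(ncol(m))) {
                si <- m["src_inst", k]; sq <- m["src_pos", k]
                bit <- bitwAnd(bitwShiftR(idx[si] - 1L, sq - 1L), 1L)
                mask <- bitwOr(mask, bitwShiftL(bit, k - 1L))
              }
              contrib[mask + 1] <- contrib[mask + 1] + pr
            }
            pos <- 1L
            while (pos <= length(rs)) {
              idx[pos] <- idx[pos] + 1L
              if (idx[pos] <= sizes[pos]) break
              idx[pos] <- 1L; pos <- pos + 1L
            }
            if (pos > length(rs)) break
          }
          prodDist <- prodDist + contrib
        }
      }
      if (totFlux > 0) {
        newDist <- prodDist / totFlux
        maxDelta <- max(maxDelta, max(abs(newDist - state[[met]])))
        state[[met]] <- newDist
      }
    }
    if (maxDelta < tol) break
  }
  state
}

# marginal MID of a carbon-position subset from an isotopomer distribution
bruteForceMID <- function(dist, positions) {
  n <- length(positions)
  mid <- numeric(n + 1)
  for (mask in 0:(length(dist) - 1)) {
    w <- 0L
    for (k in seq_along(positions))
      w <- w + bitwAnd(bitwShiftR(mask, positions[k] - 1L), 1L)
    mid[w + 1] <- mid[w + 1] + dist[mask + 1]
  }
  mid
}

bruteForceMIDs <- function(model, flux, tracer, targets) {
  state <- bruteForceIterate(model, flux, tracer)
  out <- list()
  for (i in seq_len(nrow(targets))) {
    met <- targets$metabolite[i]
    pos <- as.integer(strsplit(targets$positions[i], ",")[[1]])
    dist <- state[[met]]
    out[[targets$fragment[i]]] <- bruteForceMID(dist, pos)
  }
  out
}
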