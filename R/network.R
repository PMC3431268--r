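# Network definition parsing, validation and flux-vector algebra.

.netError <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "emufluxError", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.parseEquationSide <- function(txt) {
  # "2 PEP + E4P" -> one entry per molecule instance
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  out <- character(0)
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9]+)\\s+(\\S+)$", tm))[[1]]
    if (length(m)) out <- c(out, rep(m[3], as.integer(m[2])))
    else out <- c(out, tm)
  }
  out
}

.parseAtoms <- function(txt) {
  sides <- trimws(strsplit(txt, ":", fixed = TRUE)[[1]])
  if (length(sides) != 2)
    .netError("emufluxParseError", paste("bad atom map:", txt))
  lapply(sides, function(s) trimws(strsplit(s, "+", fixed = TRUE)[[1]]))
}

.parseCofactors <- function(txt) {
  if (is.na(txt) || txt == "-" || txt == "") return(numeric(0))
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  kv <- strsplit(trimws(parts), "=", fixed = TRUE)
  val <- vapply(kv, function(x) as.numeric(x[2]), 0)
  names(val) <- vapply(kv, `[[`, "", 1)
  if (any(!is.finite(val)))
    .netError("emufluxParseError", paste("non-finite cofactor entry:", txt))
  val
}

.buildReaction <- function(id, equation, atoms, reversible, compartment,
                           cofactors, carbons) {
  sides <- strsplit(equation, "-->", fixed = TRUE)[[1]]
  if (length(sides) != 2)
    .netError("emufluxParseError", paste0("reaction '", id, "': bad equation"))
  reactants <- .parseEquationSide(sides[1])
  products <- .parseEquationSide(sides[2])
  am <- .parseAtoms(atoms)
  lhs <- am[[1]]; rhs <- am[[2]]
  if (length(lhs) != length(reactants))
    .netError("emufluxParseError",
              paste0("reaction '", id, "': atom groups != reactant instances"))
  unmapped <- identical(rhs, ".")
  if (!unmapped && length(rhs) != length(products))
    .netError("emufluxParseError",
              paste0("reaction '", id, "': atom groups != product instances"))
  # assign letters to reactant instances
  letterSrc <- list()
  for (i in seq_along(reactants)) {
    met <- reactants[i]
    nc <- carbons[[met]]
    if (is.null(nc))
      .netError("emufluxParseError",
                paste0("reaction '", id, "': undeclared metabolite ", met))
    ltrs <- strsplit(lhs[i], "")[[1]]
    if (length(ltrs) != nc)
      .netError("emufluxCarbonMismatch",
                paste0("reaction '", id, "': ", met, " declared ", nc,
                       " carbons but atom group '", lhs[i], "' has ",
                       length(ltrs)))
    for (k in seq_along(ltrs)) {
      if (!is.null(letterSrc[[ltrs[k]]]))
        .netError("emufluxBijectionError",
                  paste0("reaction '", id, "': reactant carbon letter '",
                         ltrs[k], "' used twice"))
      letterSrc[[ltrs[k]]] <- c(inst = i, pos = k)
    }
  }
  pmap <- vector("list", length(products))
  if (!unmapped) {
    used <- character(0)
    for (j in seq_along(products)) {
      met <- products[j]
      nc <- carbons[[met]]
      if (is.null(nc))
        .netError("emufluxParseError",
                  paste0("reaction '", id, "': undeclared metabolite ", met))
      ltrs <- strsplit(rhs[j], "")[[1]]
      if (length(ltrs) != nc)
        .netError("emufluxCarbonMismatch",
                  paste0("reaction '", id, "': ", met, " declared ", nc,
                         " carbons but atom group '", rhs[j], "' has ",
                         length(ltrs)))
      src <- matrix(0L, nrow = 2, ncol = length(ltrs),
                    dimnames = list(c("src_inst", "src_pos"), NULL))
      for (k in seq_along(ltrs)) {
        if (ltrs[k] %in% used)
          .netError("emufluxBijectionError",
                    paste0("reaction '", id, "': product carbon letter '",
                           ltrs[k], "' mapped twice"))
        s <- letterSrc[[ltrs[k]]]
        if (is.null(s))
          .netError("emufluxBijectionError",
                    paste0("reaction '", id, "': product carbon letter '",
                           ltrs[k], "' has no reactant source"))
        used <- c(used, ltrs[k])
        src[, k] <- s
      }
      pmap[[j]] <- src
    }
    if (length(used) != length(letterSrc))
      .netError("emufluxBijectionError",
                paste0("reaction '", id, "': reactant carbons ",
                       paste(setdiff(names(letterSrc), used), collapse = ","),
                       " not consumed"))
  } else {
    pmap <- NULL
  }
  if (reversible && is.null(pmap))
    .netError("emufluxParseError",
              paste0("reaction '", id, "': reversible reactions must be ",
                     "fully atom-mapped"))
  list(id = id, reactants = reactants, products = products, pmap = pmap,
       reversible = reversible, compartment = compartment,
       cofactors = cofactors)
}

.validateModel <- function(model) {
  ids <- vapply(model@reactions, `[[`, "", "id")
  if (anyDuplicated(ids))
    .netError("emufluxDuplicateReaction",
              paste("duplicate reaction id:", ids[duplicated(ids)][1]))
  met <- model@metabolites
  bal <- met$name[met$role == "balanced"]
  cnt <- setNames(integer(length(bal)), bal)
  for (r in model@reactions) {
    for (m in unique(c(r$reactants, r$products)))
      if (m %in% bal) cnt[m] <- cnt[m] + 1L
  }
  if (any(cnt < 2L))
    .netError("emufluxOrphanMetabolite",
              paste("balanced metabolite in <2 reactions:",
                    paste(names(cnt)[cnt < 2L], collapse = ", ")))
  sub <- met$name[met$role == "substrate"]
  if (length(sub) != 1)
    .netError("emufluxParseError", "exactly one substrate must be declared")
  upt <- vapply(model@reactions,
                function(r) sub %in% r$reactants, TRUE)
  if (sum(upt) != 1)
    .netError("emufluxParseError",
              "exactly one substrate-uptake reaction is required")
  invisible(model)
}

#' Load an atom-mapped network definition file
#'
#' Parses the structured text dialect used by emuflux (see the packaged
#' `ccm_network.tsv` for the format: a `@metabolites` section declaring name,
#' carbon count and role, and a `@reactions` section with equation, atom map,
#' reversibility, compartment and cofactor ledger). All carbon-map bijection
#' and conservation checks run at load time; violations raise classed errors
#' (`emufluxBijectionError`, `emufluxCarbonMismatch`,
#' `emufluxDuplicateReaction`, `emufluxOrphanMetabolite`) naming the reaction.
#'
#' @param path file path.
#' @return a validated [NetworkModel-class].
#' @export
loadNetwork <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sec <- cumsum(grepl("^@", lines))
  secName <- sub("^@", "", lines[grepl("^@", lines)])
  metLines <- lines[sec == which(secName == "metabolites") & !grepl("^@", lines)]
  rxnLines <- lines[sec == which(secName == "reactions") & !grepl("^@", lines)]
  metF <- do.call(rbind, strsplit(metLines, "\t"))
  metabolites <- data.frame(name = metF[, 1],
                            carbons = as.integer(metF[, 2]),
                            role = metF[, 3], stringsAsFactors = FALSE)
  carbons <- setNames(as.list(metabolites$carbons), metabolites$name)
  reactions <- list()
  for (ln in rxnLines) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < 6)
      .netError("emufluxParseError", paste("bad reaction record:", ln))
    r <- .buildReaction(f[1], f[2], f[3], identical(f[4], "yes"), f[5],
                        .parseCofactors(f[6]), carbons)
    if (!is.null(reactions[[r$id]]))
      .netError("emufluxDuplicateReaction",
                paste("duplicate reaction id:", r$id))
    reactions[[r$id]] <- r
  }
  model <- new("NetworkModel", metabolites = metabolites,
               reactions = reactions,
               substrate = metabolites$name[metabolites$role == "substrate"])
  .validateModel(model)
}

#' Write a NetworkModel back to the network file format
#'
#' Inverse of [loadNetwork()]; `loadNetwork(writeNetwork(m, f))` reproduces a
#' structurally identical model.
#'
#' @param model a [NetworkModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@metabolites", con)
  with(model@metabolites,
       writeLines(paste(name, carbons, role, sep = "\t"), con))
  writeLines("@reactions", con)
  for (r in model@reactions) {
    # reconstruct letter groups
    nR <- length(r$reactants)
    letters26 <- letters
    offs <- cumsum(c(0, vapply(r$reactants, function(m)
      .carbonCount(model, m), 0L)))
    lhs <- vapply(seq_len(nR), function(i) {
      nc <- .carbonCount(model, r$reactants[i])
      paste(letters26[offs[i] + seq_len(nc)], collapse = "")
    }, "")
    if (is.null(r$pmap)) rhs <- "."
    else rhs <- vapply(seq_along(r$products), function(j) {
      src <- r$pmap[[j]]
      paste(letters26[offs[src["src_inst", ]] + src["src_pos", ]],
            collapse = "")
    }, "")
    eqL <- paste(r$reactants, collapse = " + ")
    eqR <- paste(r$products, collapse = " + ")
    # compress repeated instances with coefficients
    compress <- function(v) {
      rl <- rle(v)
      paste(ifelse(rl$lengths > 1, paste(rl$lengths, rl$values), rl$values),
            collapse = " + ")
    }
    eq <- paste(compress(r$reactants), "-->", compress(r$products))
    cof <- if (length(r$cofactors) == 0) "-" else
      paste(names(r$cofactors), r$cofactors, sep = "=", collapse = ",")
    writeLines(paste(r$id, eq,
                     paste(paste(lhs, collapse = " + "), ":",
                           paste(rhs, collapse = " + ")),
                     if (r$reversible) "yes" else "no",
                     r$compartment, cof, sep = "\t"), con)
  }
  invisible(path)
}

.carbonCount <- function(model, met) {
  i <- match(met, model@metabolites$name)
  if (is.na(i)) .netError("emufluxParseError", paste("unknown metabolite", met))
  model@metabolites$carbons[i]
}

.metRole <- function(model, met) {
  model@metabolites$role[match(met, model@metabolites$name)]
}

#' The packaged fermentative central-carbon-metabolism network
#'
#' Returns the default 60-reaction atom-mapped model of fermenting
#' S. cerevisiae central carbon metabolism: glycolysis, oxidative and
#' non-oxidative pentose phosphate pathway (two transketolases, one
#' transaldolase), the glycerol branch, pyruvate decarboxylase, the
#' acetaldehyde node (alcohol dehydrogenase, NADP+-dependent acetaldehyde
#' dehydrogenase, acetyl-CoA synthetase), pyruvate carboxylase with
#' mitochondrial oxaloacetate import, a TCA segment supporting succinate
#' formation, amino-acid synthesis with explicit carbon maps, biomass drains,
#' and an external NADPH-consuming acetoin-reduction reaction.
#'
#' @return a validated [NetworkModel-class] with 60 reactions.
#' @export
defaultCCMNetwork <- function() {
  if (is.null(.pkgCache$ccm))
    .pkgCache$ccm <- loadNetwork(system.file("extdata", "ccm_network.tsv",
                                             package = "emuflux",
                                             mustWork = TRUE))
  .pkgCache$ccm
}

.pkgCache <- new.env(parent = emptyenv())

#' Reaction ids of a model
#' @param model a [NetworkModel-class].
#' @return character vector.
#' @export
reactionIds <- function(model) names(model@reactions)

#' Stoichiometric matrix over balanced metabolites
#'
#' Entry (i, j) is the signed molar coefficient of balanced metabolite i in
#' reaction j; substrate and external species are excluded. Reversible
#' reactions contribute a single net-flux column.
#'
#' @param model a [NetworkModel-class].
#' @return numeric matrix, balanced metabolites x reactions.
#' @export
stoichiometricMatrix <- function(model) {
  bal <- model@metabolites$name[model@metabolites$role == "balanced"]
  S <- matrix(0, length(bal), length(model@reactions),
              dimnames = list(bal, names(model@reactions)))
  for (r in model@reactions) {
    for (m in r$reactants) if (m %in% bal) S[m, r$id] <- S[m, r$id] - 1
    for (m in r$products) if (m %in% bal) S[m, r$id] <- S[m, r$id] + 1
  }
  S
}

#' Construct a FluxVector
#'
#' @param net named numeric of net fluxes (mol per 100 mol glucose).
#' @param exchange named numeric in [0, 1) for reversible reactions
#'   (missing reversible reactions default to 0).
#' @param exchangeScale scale mapping the bounded exchange parameter to flux
#'   units; the exchange magnitude is `x / (1 - x) * exchangeScale`.
#' @return a [FluxVector-class].
#' @export
fluxVector <- function(net, exchange = numeric(0), exchangeScale = 100) {
  if (is.null(names(net))) stop("net fluxes must be named")
  if (length(exchange) && (any(exchange < 0) || any(exchange >= 1)))
    stop("exchange parameters must lie in [0, 1)")
  new("FluxVector", net = net, exchange = exchange,
      exchangeScale = exchangeScale)
}

#' Net fluxes of a FluxVector
#' @param x a [FluxVector-class].
#' @return named numeric.
#' @export
netFlux <- function(x) x@net

#' Exchange magnitudes of a FluxVector, in flux units
#' @param x a [FluxVector-class].
#' @return named numeric (x / (1 - x) * exchangeScale).
#' @export
exchangeMagnitude <- function(x) {
  e <- x@exchange
  e / (1 - e) * x@exchangeScale
}

#' Per-metabolite balance report for a flux vector
#'
#' Computes the residual S v for every balanced metabolite and lists
#' irreversibility violations (negative net flux on an irreversible
#' reaction). A reporting operation: it never raises an error.
#'
#' @param model a [NetworkModel-class].
#' @param flux a [FluxVector-class] or named numeric of net fluxes.
#' @return list with `residuals` (data.frame metabolite, residual),
#'   `maxAbsResidual`, and `irreversibilityViolations`.
#' @export
validateFluxBalance <- function(model, flux) {
  v <- if (is(flux, "FluxVector")) flux@net else flux
  S <- stoichiometricMatrix(model)
  ids <- colnames(S)
  vv <- setNames(numeric(length(ids)), ids)
  vv[intersect(names(v), ids)] <- v[intersect(names(v), ids)]
  res <- drop(S %*% vv)
  rev <- vapply(model@reactions, `[[`, TRUE, "reversible")
  irr <- names(vv)[!rev[names(vv)] & vv < -1e-9]
  list(residuals = data.frame(metabolite = names(res), residual = unname(res)),
       maxAbsResidual = max(abs(res)),
       irreversibilityViolations = irr)
}

#' Build a free-flux parameterization
#'
#' Splits the reactions into fixed (equality constraints, e.g. the glucose
#' uptake normalization), free, and dependent sets; the dependent fluxes are
#' obtained by solving the balanced-metabolite block of S v = 0. Errors if
#' the dependent block is singular (the chosen free set is not a valid basis).
#'
#' @param model a [NetworkModel-class].
#' @param free character, free reaction ids.
#' @param fixed named numeric of equality constraints (default `c(glk = 100)`
#'   when a reaction `glk` exists).
#' @return a [FreeFluxParam-class].
#' @export
freeFluxParam <- function(model, free, fixed = NULL) {
  S <- stoichiometricMatrix(model)
  ids <- colnames(S)
  if (is.null(fixed)) {
    fixed <- if ("glk" %in% ids) c(glk = 100) else numeric(0)
  }
  dep <- setdiff(ids, c(free, names(fixed)))
  if (length(dep) != nrow(S))
    .netError("emufluxBasisError",
              sprintf("free set size %d does not match the %d degrees of freedom (%d dependent vs %d balanced metabolites)",
                      length(free), ncol(S) - nrow(S) - length(fixed),
                      length(dep), nrow(S)))
  qrDep <- qr(S[, dep, drop = FALSE])
  if (qrDep$rank < length(dep))
    .netError("emufluxBasisError",
              "dependent stoichiometric block is singular; choose another free set")
  new("FreeFluxParam", free = free, fixed = fixed, dep = dep, qrDep = qrDep,
      Sknown = S[, c(names(fixed), free), drop = FALSE], reactionIds = ids)
}

#' Reconstruct a full flux vector from free-flux values
#'
#' Solves the dependent fluxes from the stoichiometric balance so that
#' S v = 0 holds exactly (to solver precision) and the equality constraints
#' are honoured exactly.
#'
#' @param param a [FreeFluxParam-class].
#' @param values numeric, one value per `param@free` (names optional).
#' @param fixed optional named numeric overriding the stored equality
#'   constraints (same names).
#' @param exchange named numeric exchange parameters for the returned vector.
#' @return a [FluxVector-class].
#' @export
fluxFromFree <- function(param, values, fixed = NULL, exchange = numeric(0)) {
  if (length(values) != length(param@free))
    .netError("emufluxBasisError", "wrong number of free-flux values")
  fx <- param@fixed
  if (!is.null(fixed)) {
    if (!all(names(fixed) %in% names(fx)))
      .netError("emufluxBasisError", "unknown fixed-flux override")
    fx[names(fixed)] <- fixed
  }
  known <- c(fx, setNames(as.numeric(values), param@free))
  rhs <- -param@Sknown %*% known
  vdep <- qr.coef(param@qrDep, rhs)
  v <- setNames(numeric(length(param@reactionIds)), param@reactionIds)
  v[names(known)] <- known
  v[param@dep] <- drop(vdep)
  fluxVector(v, exchange = exchange)
}
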