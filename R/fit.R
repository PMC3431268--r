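# Weighted least-squares flux estimation: objective, single bounded
# Levenberg-Marquardt fit, and multi-start estimation with
# convergent-solution averaging.

#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

.penaltyWeight <- 100

#' Assemble a flux-fitting problem
#'
#' Bundles the network, tracer, fragment panel, SFL and net-flux measurement
#' tables, the free-flux parameterization and the optimizer settings. The
#' default free set fixes glucose uptake at 100 and leaves 21 net degrees of
#' freedom; exchange fluxes are held at their configured values.
#'
#' @param model a [NetworkModel-class].
#' @param sfl data.frame `fragment`, `value`, `sd` (SFL units).
#' @param fluxes data.frame `reaction`, `value`, `sd` (per 100 glucose).
#' @param tracer a [SubstrateLabeling-class].
#' @param panel fragment panel data.frame.
#' @param free free-flux reaction ids.
#' @param fixed named equality constraints.
#' @param exchange fixed exchange parameters in [0, 1).
#' @param nStarts number of multi-start optimizations.
#' @param seed RNG seed for start generation (mandatory for multi-start).
#' @param delta convergent-solution filter: keep converged solutions with
#'   SSR <= min(SSR) * (1 + delta).
#' @param maxiter per-start optimizer iteration cap.
#' @param bounds optional list `lower`/`upper` named over the free fluxes;
#'   defaults to lower 0 and upper 3 * measured + 10 (150 when unmeasured).
#' @return a [FitProblem-class].
#' @export
fitProblem <- function(model, sfl, fluxes, tracer = substrateLabeling(),
                       panel = defaultFragmentPanel(),
                       free = defaultFreeFluxes(), fixed = NULL,
                       exchange = defaultExchange(), nStarts = 100,
                       seed = 1L, delta = 0.05, maxiter = 150,
                       bounds = NULL) {
  stopifnot(all(c("fragment", "value", "sd") %in% names(sfl)),
            all(c("reaction", "value", "sd") %in% names(fluxes)))
  if (any(sfl$sd <= 0) || any(fluxes$sd <= 0))
    stop("measurement standard deviations must be positive")
  if (!all(sfl$fragment %in% panel$fragment))
    stop("SFL measurement for a fragment absent from the panel: ",
         paste(setdiff(sfl$fragment, panel$fragment), collapse = ", "))
  if (!all(fluxes$reaction %in% reactionIds(model)))
    stop("flux measurement for an unknown reaction: ",
         paste(setdiff(fluxes$reaction, reactionIds(model)), collapse = ", "))
  param <- freeFluxParam(model, free, fixed)
  if (is.null(bounds)) {
    up <- setNames(rep(150, length(free)), free)
    mIdx <- match(free, fluxes$reaction)
    hit <- !is.na(mIdx)
    up[hit] <- 3 * abs(fluxes$value[mIdx[hit]]) + 10
    bounds <- list(lower = setNames(rep(0, length(free)), free), upper = up)
  }
  new("FitProblem", model = model, tracer = tracer, panel = panel,
      sfl = sfl, fluxes = fluxes, param = param, exchange = exchange,
      settings = list(nStarts = nStarts, seed = seed, delta = delta,
                      maxiter = maxiter, bounds = bounds),
      cache = new.env(parent = emptyenv()))
}

#' Number of data items in a fit problem
#' @param problem a [FitProblem-class].
#' @return integer (SFL measurements + flux measurements).
#' @export
nDataItems <- function(problem) nrow(problem@sfl) + nrow(problem@fluxes)

.problemSystem <- function(problem) {
  if (is.null(problem@cache$system)) {
    need <- problem@panel[problem@panel$fragment %in% problem@sfl$fragment, ]
    problem@cache$system <- emuDecompose(problem@model, need)
  }
  problem@cache$system
}

.problemResiduals <- function(problem, freeValues, smoothEps = 0) {
  fl <- fluxFromFree(problem@param, freeValues, exchange = problem@exchange)
  net <- fl@net
  rev <- vapply(problem@model@reactions, `[[`, TRUE, "reversible")
  irr <- net[!rev[names(net)]]
  pen <- .penaltyWeight *
    (if (smoothEps > 0) (sqrt(irr^2 + smoothEps^2) - irr) / 2 else
       -pmin(irr, 0))
  sim <- simulateSFLs(problem@model, fl, problem@tracer, problem@panel,
                      system = .problemSystem(problem), fluxFloor = 1e-6,
                      smoothEps = smoothEps)
  simv <- setNames(sim$sfl, sim$fragment)
  rSfl <- (simv[problem@sfl$fragment] - problem@sfl$value) / problem@sfl$sd
  rFlx <- (net[problem@fluxes$reaction] - problem@fluxes$value) /
    problem@fluxes$sd
  list(data = c(rSfl, rFlx), penalty = pen, flux = fl, sim = simv)
}

#' Weighted sum-of-squares objective
#'
#' SSR = sum over all data items of ((simulated - measured) / sd)^2,
#' evaluated at the given free-flux values. Deterministic.
#'
#' @param problem a [FitProblem-class].
#' @param freeValues numeric, one value per free flux.
#' @return list with `ssr` (scalar), `residuals` (named weighted residual
#'   vector over all data items), and `flux` (the reconstructed
#'   [FluxVector-class]).
#' @export
fitObjective <- function(problem, freeValues) {
  r <- .problemResiduals(problem, freeValues)
  list(ssr = sum(r$data^2), residuals = r$data, flux = r$flux)
}

#' Single bounded least-squares fit from one start
#'
#' Runs bounded Levenberg-Marquardt on the weighted residuals (plus a
#' soft penalty keeping dependent irreversible fluxes non-negative).
#' Optimizer exceptions are caught and recorded as a non-converged solution.
#'
#' @param problem a [FitProblem-class].
#' @param start numeric start vector within bounds (precondition).
#' @return list: `free` (solution), `ssr`, `converged`, `info`, `message`.
#' @export
fitOnce <- function(problem, start) {
  b <- problem@settings$bounds
  if (any(start < b$lower - 1e-9) || any(start > b$upper + 1e-9))
    .netError("emufluxBoundsError", "start violates the optimization bounds")
  nIrrev <- sum(!vapply(problem@model@reactions, `[[`, TRUE, "reversible"))
  rev <- vapply(problem@model@reactions, `[[`, TRUE, "reversible")
  # stage 1: the flux-measurement residuals are affine in the free fluxes;
  # solve that bounded linear least-squares problem exactly (active set) so
  # the full optimization starts from a measurement-consistent region
  if (nrow(problem@fluxes) > 0) {
    lin <- tryCatch(.linearStage(problem, start),
                    error = function(e) NULL)
    # keep a fraction of the random start so the multi-start still probes
    # distinct basins, clamped to the statistically meaningful neighbourhood
    # of the measurement-consistent point (5 measurement SDs per flux)
    if (!is.null(lin)) {
      sdClamp <- setNames(rep(5, length(start)), problem@param@free)
      mIdx <- match(problem@param@free, problem@fluxes$reaction)
      sdClamp[!is.na(mIdx)] <- 5 * problem@fluxes$sd[mIdx[!is.na(mIdx)]]
      delta <- pmin(pmax(0.1 * (start - lin), -sdClamp), sdClamp)
      start <- pmin(pmax(lin + delta, b$lower), b$upper)
    }
  }
  nSfl <- nrow(problem@sfl)
  # soften very tight SFL weights during navigation (continuation): the
  # first pass weights SFLs as if their SD were at least 0.3 units
  soften <- pmin(problem@sfl$sd / 0.3, 1)
  mkfn <- function(eps, soft = FALSE) function(par) {
    r <- tryCatch(.problemResiduals(problem, par, smoothEps = eps),
                  error = function(e) NULL)
    if (is.null(r)) return(rep(1e6, nDataItems(problem) + nIrrev))
    d <- r$data
    if (soft) d[seq_len(nSfl)] <- d[seq_len(nSfl)] * soften
    c(d, r$penalty)
  }
  # stage 2: smoothed, softened objective (differentiable across flux sign
  # changes), then a sharp polish with the true weights so the reported
  # optimum is that of the exact model
  ctl <- nls.lm.control(maxiter = problem@settings$maxiter,
                        ftol = 1e-12, ptol = 1e-10)
  res <- tryCatch({
    r2a <- nls.lm(par = start, lower = b$lower, upper = b$upper,
                  fn = mkfn(0.1, soft = TRUE), control = ctl)
    nls.lm(par = r2a$par, lower = b$lower, upper = b$upper, fn = mkfn(0),
           control = ctl)
  }, error = function(e) NULL)
  if (is.null(res))
    return(list(free = start, ssr = Inf, converged = FALSE, info = -1L,
                message = "optimizer exception"))
  r <- tryCatch(.problemResiduals(problem, res$par),
                error = function(e) NULL)
  if (is.null(r))
    return(list(free = res$par, ssr = Inf, converged = FALSE, info = -1L,
                message = "simulation failure at solution"))
  ok <- res$info %in% 1:3 && max(abs(r$penalty)) < 1e-6
  list(free = setNames(res$par, problem@param@free), ssr = sum(r$data^2),
       converged = ok, info = res$info, message = res$message)
}

# Affine map of the measured net fluxes in the free values, cached on the
# problem: net_meas(par) = M par + m0.
.linearMap <- function(problem) {
  if (is.null(problem@cache$linMap)) {
    nf <- length(problem@param@free)
    meas <- problem@fluxes$reaction
    m0 <- fluxFromFree(problem@param, numeric(nf))@net[meas]
    M <- vapply(seq_len(nf), function(j) {
      e <- numeric(nf); e[j] <- 1
      fluxFromFree(problem@param, e)@net[meas] - m0
    }, numeric(length(meas)))
    problem@cache$linMap <- list(M = matrix(M, nrow = length(meas)), m0 = m0)
  }
  problem@cache$linMap
}

# bounded-variable linear least squares by active set (BVLS), SVD-based
# inner solves so rank deficiency is handled
.bvls <- function(A, y, lower, upper, maxPasses = 60) {
  n <- ncol(A)
  x <- pmin(pmax(numeric(n), lower), upper)
  state <- integer(n)  # 0 free, -1 at lower, +1 at upper
  solveFree <- function(freeIdx, x) {
    r <- y - A[, state != 0, drop = FALSE] %*% x[state != 0]
    if (!length(freeIdx)) return(x)
    Af <- A[, freeIdx, drop = FALSE]
    sv <- svd(Af)
    keep <- sv$d > max(sv$d[1], 1e-12) * 1e-10
    z <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], r)) / sv$d[keep])
    x[freeIdx] <- z
    x
  }
  for (pass in seq_len(maxPasses)) {
    freeIdx <- which(state == 0)
    xt <- solveFree(freeIdx, x)
    viol <- which((xt < lower - 1e-12 | xt > upper + 1e-12) & state == 0)
    if (length(viol)) {
      w <- viol[which.max(pmax(lower[viol] - xt[viol], xt[viol] - upper[viol]))]
      state[w] <- if (xt[w] < lower[w]) -1L else 1L
      x[w] <- if (state[w] < 0) lower[w] else upper[w]
      next
    }
    x <- xt
    # KKT: release bound variables whose gradient pulls inward
    g <- drop(crossprod(A, A %*% x - y))
    rel <- which((state == -1L & g < -1e-10) | (state == 1L & g > 1e-10))
    if (!length(rel)) break
    state[rel[which.max(abs(g[rel]))]] <- 0L
  }
  pmin(pmax(x, lower), upper)
}

# exact solution of the bounded affine flux-measurement least squares
.linearStage <- function(problem, start) {
  lm <- .linearMap(problem)
  b <- problem@settings$bounds
  W <- 1 / problem@fluxes$sd
  A <- lm$M * W
  y <- (problem@fluxes$value - lm$m0) * W
  .bvls(A, y, b$lower, b$upper)
}

#' Select the convergent subset of multi-start solutions
#'
#' A solution is convergent when its optimizer converged and its SSR lies
#' within a factor (1 + delta) of the best converged SSR.
#'
#' @param ssr numeric vector of per-start SSR values.
#' @param converged logical vector (default all TRUE).
#' @param delta relative SSR tolerance above the best solution.
#' @return logical vector marking the convergent subset.
#' @export
summarizeConvergent <- function(ssr, converged = rep(TRUE, length(ssr)),
                                delta = 0.05) {
  if (!any(converged)) return(rep(FALSE, length(ssr)))
  best <- min(ssr[converged])
  converged & ssr <= best * (1 + delta) + 1e-12
}

#' Multi-start flux estimation with convergent-solution averaging
#'
#' Draws `nStarts` start vectors uniformly within the bounds from the seeded
#' generator, fits each, filters the convergent subset (optimizer success and
#' SSR within (1 + delta) of the best), and reports per-reaction means and
#' standard deviations of the full net-flux vectors across that subset.
#' Bit-reproducible given the seed.
#'
#' @param problem a [FitProblem-class].
#' @param nStarts,seed optional overrides of the problem settings.
#' @return a [FitResult-class].
#' @export
fitMultistart <- function(problem, nStarts = NULL, seed = NULL) {
  st <- problem@settings
  if (!is.null(nStarts)) st$nStarts <- nStarts
  if (!is.null(seed)) st$seed <- seed
  if (is.null(st$seed)) stop("a seed is required for multi-start fitting")
  b <- st$bounds
  nf <- length(problem@param@free)
  runner <- function() {
    set.seed(st$seed)
    starts <- matrix(runif(st$nStarts * nf, rep(b$lower, each = st$nStarts),
                           rep(b$upper, each = st$nStarts)),
                     nrow = st$nStarts)
    lapply(seq_len(st$nStarts), function(i) fitOnce(problem, starts[i, ]))
  }
  sols <- .withPreservedRNG(runner)
  ssr <- vapply(sols, `[[`, 0, "ssr")
  conv <- vapply(sols, `[[`, TRUE, "converged")
  if (!any(conv))
    .netError("emufluxNoConvergence",
              "no start converged; increase nStarts or widen the bounds")
  sub <- summarizeConvergent(ssr, conv, st$delta)
  nets <- vapply(sols[sub], function(s)
    fluxFromFree(problem@param, s$free, exchange = problem@exchange)@net,
    numeric(length(problem@param@reactionIds)))
  mns <- rowMeans(nets)
  sds <- apply(nets, 1, sd)
  if (sum(sub) == 1) sds[] <- 0
  bestIdx <- which(conv & ssr == min(ssr[conv]))[1]
  best <- fluxFromFree(problem@param, sols[[bestIdx]]$free,
                       exchange = problem@exchange)
  resid <- fitObjective(problem, sols[[bestIdx]]$free)$residuals
  new("FitResult",
      fluxMeans = data.frame(reaction = names(mns), mean = unname(mns),
                             sd = unname(sds)),
      starts = data.frame(start = seq_along(sols), ssr = ssr,
                          converged = conv, inSubset = sub),
      nConvergent = sum(sub), best = best,
      solutions = lapply(sols, `[[`, "free"),
      residuals = data.frame(item = names(resid),
                             residual = unname(resid)),
      settings = st)
}

# run fn with an isolated, seeded RNG stream, restoring the caller's state
.withPreservedRNG <- function(fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  fn()
}

#' Flux means of a fit result
#' @param result a [FitResult-class].
#' @return data.frame `reaction`, `mean`, `sd`.
#' @export
fluxMeans <- function(result) result@fluxMeans

#' Write a fit result as a flux table plus JSON run metadata
#'
#' @param result a [FitResult-class].
#' @param path CSV output path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeFitResult <- function(result, path) {
  utils::write.csv(result@fluxMeans, path, row.names = FALSE)
  meta <- list(seed = result@settings$seed,
               nStarts = result@settings$nStarts,
               nConvergent = result@nConvergent,
               delta = result@settings$delta,
               minSSR = min(result@starts$ssr[result@starts$converged]))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
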