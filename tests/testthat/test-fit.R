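# weighted least-squares estimation: objective, single fits, multi-start

toyFitProblem <- function(r4val = 25, r4sd = 1, xoutval = 95, xoutsd = 2,
                          sflData = NULL, seed = 1) {
  m <- loadNetwork(toySplitPath())
  if (is.null(sflData))
    sflData <- data.frame(fragment = character(0), value = numeric(0),
                          sd = numeric(0))
  fitProblem(m, sfl = sflData,
             fluxes = data.frame(reaction = c("r4", "xout"),
                                 value = c(r4val, xoutval),
                                 sd = c(r4sd, xoutsd)),
             tracer = substrateLabeling(),
             panel = toySplitTargets(),
             free = c("r1", "r2", "r4"), fixed = c(up = 100),
             exchange = c(r1 = 0.2), seed = seed)
}

test_that("the objective is zero at the generating fluxes (self-consistency)", {
  m <- defaultCCMNetwork()
  cfg <- generatorConfig(condition = 0, sflSd = 0, fluxRelSd = 0, seed = 2)
  ds <- generateDataset(cfg, m)
  prob <- fitProblem(m, ds@sfl, ds@fluxes, seed = 2)
  truth <- ds@provenance$trueNet[defaultFreeFluxes()]
  expect_lt(fitObjective(prob, truth)$ssr, 1e-10)
  # perturbing one measured flux by one SD adds ~1 to the SSR
  ds2 <- ds
  ds2@fluxes$value[1] <- ds2@fluxes$value[1] + ds2@fluxes$sd[1]
  prob2 <- fitProblem(m, ds2@sfl, ds2@fluxes, seed = 2)
  expect_equal(fitObjective(prob2, truth)$ssr, 1, tolerance = 1e-8)
})

test_that("the SSR matches hand arithmetic on a two-measurement problem", {
  prob <- toyFitProblem(r4val = 20, r4sd = 2, xoutval = 90, xoutsd = 5)
  o <- fitObjective(prob, c(40, 30, 25))  # r4 = 25, xout = 95
  expect_equal(o$ssr, (25 - 20)^2 / 4 + (95 - 90)^2 / 25, tolerance = 1e-9)
})

test_that("fitOnce honours its preconditions and fixed points", {
  m <- defaultCCMNetwork()
  cfg <- generatorConfig(condition = 0, sflSd = 0, fluxRelSd = 0, seed = 2)
  ds <- generateDataset(cfg, m)
  prob <- fitProblem(m, ds@sfl, ds@fluxes, seed = 2)
  truth <- ds@provenance$trueNet[defaultFreeFluxes()]
  s <- fitOnce(prob, truth)
  expect_true(s$converged)
  expect_lt(s$ssr, 1e-8)
  expect_lt(max(abs(s$free - truth)), 1e-4)
  bad <- truth; bad[1] <- -5
  expect_error(fitOnce(prob, bad), class = "emufluxBoundsError")
})

test_that("the optimum matches an exhaustive grid search on a toy problem", {
  m <- loadNetwork(toySplitPath())
  tracer <- substrateLabeling()
  truthFlux <- toySplitFlux(r1 = 40, r2 = 30, r3 = 30, r4 = 25, x1 = 0.2)
  sim <- simulateSFLs(m, truthFlux, tracer, toySplitTargets())
  sflData <- data.frame(fragment = sim$fragment, value = sim$sfl, sd = 0.3)
  prob <- toyFitProblem(r4val = 25, r4sd = 0.5, xoutval = 95, xoutsd = 2,
                        sflData = sflData)
  # grid-search oracle over (r1, r2) with r4 at its measured optimum slice
  gridSSR <- function(r1, r2) fitObjective(prob, c(r1, r2, 25))$ssr
  lo <- c(20, 10); hi <- c(60, 50)
  best <- NULL
  for (level in 1:3) {
    g1 <- seq(lo[1], hi[1], length.out = 13)
    g2 <- seq(lo[2], hi[2], length.out = 13)
    ssr <- outer(g1, g2, Vectorize(gridSSR))
    ij <- which(ssr == min(ssr), arr.ind = TRUE)[1, ]
    best <- c(g1[ij[1]], g2[ij[2]])
    span <- c(g1[2] - g1[1], g2[2] - g2[1])
    lo <- best - span; hi <- best + span
  }
  s <- fitOnce(prob, c(35, 35, 25))
  expect_true(s$converged)
  # grid resolution at level 3 is ~0.02; the continuous optimizer must agree
  expect_lt(abs(s$free[["r1"]] - best[1]), 0.05)
  expect_lt(abs(s$free[["r2"]] - best[2]), 0.05)
  # and both should sit at the generating values (zero-noise data)
  expect_lt(abs(s$free[["r1"]] - 40), 0.02)
  expect_lt(abs(s$free[["r2"]] - 30), 0.02)
})

test_that("the convergent-subset rule applies exactly as documented", {
  expect_equal(summarizeConvergent(c(1.0, 1.02, 1.2), delta = 0.05),
               c(TRUE, TRUE, FALSE))
  expect_equal(summarizeConvergent(c(1, 10), delta = 0.05), c(TRUE, FALSE))
  expect_equal(summarizeConvergent(rep(2, 5), delta = 0.05), rep(TRUE, 5))
  expect_equal(summarizeConvergent(c(5, 1), converged = c(TRUE, FALSE)),
               c(TRUE, FALSE))
})

test_that("multi-start estimation is seeded, reproducible and averaged", {
  m <- loadNetwork(toySplitPath())
  tracer <- substrateLabeling()
  truthFlux <- toySplitFlux()
  sim <- simulateSFLs(m, truthFlux, tracer, toySplitTargets())
  sflData <- data.frame(fragment = sim$fragment, value = sim$sfl, sd = 0.3)
  prob <- toyFitProblem(sflData = sflData, seed = 4)
  one <- fitMultistart(prob, nStarts = 1)
  expect_equal(one@nConvergent, 1L)
  expect_true(all(one@fluxMeans$sd == 0))
  a <- fitMultistart(prob, nStarts = 3)
  b <- fitMultistart(prob, nStarts = 3)
  expect_identical(a@fluxMeans, b@fluxMeans)
  expect_identical(a@starts, b@starts)
  # reported means satisfy the stoichiometric balance
  S <- stoichiometricMatrix(m)
  mn <- setNames(a@fluxMeans$mean, a@fluxMeans$reaction)
  expect_lt(max(abs(S %*% mn[colnames(S)])) / max(abs(mn)), 1e-6)
})

test_that("doubling measurement SDs rescales the SSR but not the optimum", {
  m <- loadNetwork(toySplitPath())
  emptySfl <- data.frame(fragment = character(0), value = numeric(0),
                         sd = numeric(0))
  mkProb <- function(scale) {
    fitProblem(m, sfl = emptySfl,
               fluxes = data.frame(
                 reaction = c("r4", "xout", "wout", "r1"),
                 value = c(24, 93, 4, 42),
                 sd = scale * c(1, 2, 1, 2)),
               tracer = substrateLabeling(), panel = toySplitTargets(),
               free = c("r1", "r2", "r4"), fixed = c(up = 100),
               exchange = c(r1 = 0.2), seed = 1)
  }
  s1 <- fitOnce(mkProb(1), c(40, 30, 25))
  s2 <- fitOnce(mkProb(2), c(40, 30, 25))
  expect_lt(max(abs(s1$free - s2$free)), 1e-4)
  expect_equal(s2$ssr, s1$ssr / 4, tolerance = 1e-4)
})
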