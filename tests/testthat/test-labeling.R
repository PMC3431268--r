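# labeling simulator: EMU decomposition, MID simulation, SFL,
# natural-abundance correction

test_that("EMU decomposition finds the minimal units for a linear chain", {
  path <- writeToyNetwork(
    c("A.ext\t2\tsubstrate", "B\t2\tbalanced", "C.ext\t2\texternal"),
    c("up\tA.ext --> B\tab : ab\tno\tc\t-",
      "out\tB --> C.ext\tab : ab\tno\te\t-"))
  m <- loadNetwork(path)
  sys <- emuDecompose(m, data.frame(fragment = "B12", metabolite = "B",
                                    positions = "1,2", moiety = "",
                                    family = "x"))
  expect_equal(sort(c(sys$emus$key, sys$inputKeys)),
               sort(c("B|1,2", "A.ext|1,2")))
})

test_that("EMU simulation matches brute-force isotopomer enumeration", {
  m <- loadNetwork(toySplitPath())
  targets <- toySplitTargets()
  tracer <- substrateLabeling(fraction = 0.4, purity = 0.99)
  for (fl in list(toySplitFlux(),
                  toySplitFlux(r1 = 10, r2 = 55, r3 = 35, r4 = 35, x1 = 0.5),
                  toySplitFlux(r1 = 80, r2 = 5, r3 = 15, r4 = 1, x1 = 0))) {
    mids <- simulateMIDs(m, fl, tracer, targets)
    oracle <- bruteForceMIDs(m, fl, tracer, targets)
    for (f in names(mids))
      expect_lt(max(abs(mids[[f]] - oracle[[f]])), 1e-8)
  }
})

test_that("degenerate tracers produce the expected MIDs", {
  m <- loadNetwork(toySplitPath())
  targets <- toySplitTargets()
  # no label, pure-12C remainder: all mass at m0
  none <- substrateLabeling(fraction = 0, remainder = "pure12C")
  mids <- simulateMIDs(m, toySplitFlux(), none, targets)
  for (f in names(mids)) {
    expect_equal(mids[[f]][1], 1, tolerance = 1e-12)
    expect_lt(max(abs(mids[[f]][-1])), 1e-12)
  }
  # fully uniformly labeled: all mass at mn (carbon conservation)
  full <- substrateLabeling(fraction = 1, purity = 1, remainder = "pure12C",
                            mode = "uniform")
  mids <- simulateMIDs(m, toySplitFlux(), full, targets)
  for (f in names(mids)) {
    n <- length(mids[[f]])
    expect_equal(mids[[f]][n], 1, tolerance = 1e-12)
  }
})

test_that("every simulated MID stays normalized (property)", {
  m <- loadNetwork(toySplitPath())
  targets <- toySplitTargets()
  tracer <- substrateLabeling()
  set.seed(11)
  for (i in 1:15) {
    fl <- toySplitFlux(r1 = runif(1, 1, 80), r2 = runif(1, 1, 80),
                       r3 = runif(1, 5, 80), r4 = runif(1, 0, 4),
                       x1 = runif(1, 0, 0.8))
    mids <- simulateMIDs(m, fl, tracer, targets)
    for (f in names(mids)) {
      expect_lt(abs(sum(mids[[f]]) - 1), 1e-9)
      expect_gt(min(mids[[f]]), -1e-12)
    }
  }
})

test_that("substrate EMU MIDs mix linearly in the tracer fraction", {
  nC <- 6
  pos <- c(1, 3, 4)
  m0 <- emuflux:::substrateMID
  a <- m0(substrateLabeling(fraction = 0), pos, nC)
  b <- m0(substrateLabeling(fraction = 1), pos, nC)
  for (f in c(0.25, 0.4, 0.8)) {
    mix <- m0(substrateLabeling(fraction = f), pos, nC)
    expect_equal(mix, (1 - f) * a + f * b, tolerance = 1e-12)
  }
})

test_that("alanine traces back to cytosolic pyruvate in the full network", {
  m <- defaultCCMNetwork()
  sys <- emuDecompose(m, data.frame(fragment = "ala", metabolite = "ALA",
                                    positions = "1,2,3", moiety = "",
                                    family = "x"))
  expect_true("PYR.c|1,2,3" %in% sys$emus$key)
})

test_that("unreachable fragments and dead pools raise named errors", {
  m <- loadNetwork(toySplitPath())
  expect_error(
    emuDecompose(m, data.frame(fragment = "bad", metabolite = "X.ext",
                               positions = "1,2", moiety = "", family = "x")),
    class = "emufluxUnreachableFragment")
  # zero production of a required pool under degenerate fluxes
  fl <- toySplitFlux(r1 = 0, r2 = 0, r3 = 50, r4 = 0, x1 = 0)
  tgt <- data.frame(fragment = "X", metabolite = "X", positions = "1,2,3",
                    moiety = "", family = "x")
  expect_error(simulateMIDs(m, fl, substrateLabeling(), tgt),
               class = "emufluxSingularEMU")
})

test_that("the SFL statistic evaluates its defining formula", {
  expect_equal(sfl(c(1, 0)), 0)
  expect_equal(sfl(c(0, 0, 1)), 200)
  expect_equal(sfl(c(0.6, 0.3, 0.1)), 50)
  expect_error(sfl(c(0, 0, 0)), class = "emufluxZeroMID")
})

test_that("SFL strictly increases when mass moves to heavier isotopomers", {
  set.seed(5)
  for (i in 1:10) {
    mid <- runif(5); mid <- mid / sum(mid)
    from <- sample(4, 1)
    to <- if (from == 4) 5L else sample((from + 1):5, 1)
    shift <- mid
    eps <- mid[from] / 2
    shift[from] <- shift[from] - eps; shift[to] <- shift[to] + eps
    expect_gt(sfl(shift), sfl(mid))
  }
})

test_that("natural-abundance forward model matches the binomial oracle", {
  p <- 0.0107
  expect_equal(addNaturalAbundance(c(1, 0), ""), c(1, 0))
  one <- addNaturalAbundance(c(1, 0), "C1")
  expect_equal(one[1:2], c(1 - p, p), tolerance = 1e-12)
  two <- addNaturalAbundance(c(1, 0), "C2")
  binom <- dbinom(0:2, 2, p)
  expect_equal(two[1:3], binom, tolerance = 1e-12)
  expect_equal(two[2], 2 * p * (1 - p), tolerance = 1e-12)
})

test_that("natural-abundance correction inverts the forward model", {
  expect_equal(correctNaturalAbundance(c(0.7, 0.3), ""), c(0.7, 0.3),
               ignore_attr = TRUE)
  set.seed(9)
  for (i in 1:10) {
    mid <- runif(5); mid <- mid / sum(mid)
    raw <- addNaturalAbundance(mid, "C8H12NO4")
    back <- correctNaturalAbundance(raw, "C8H12NO4", n = 4)
    expect_lt(max(abs(back - mid)), 1e-8)
  }
  # binomially contaminated pure fragment is restored
  raw <- addNaturalAbundance(c(1, 0), "C2")
  expect_equal(correctNaturalAbundance(raw, "C2", n = 1), c(1, 0),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("moiety distributions are valid distributions", {
  for (f in c("C10H14O9", "C4H12N2O2", "C3H9N2", "-")) {
    d <- moietyDistribution(f)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_true(all(d >= 0))
  }
})

test_that("the default panel has 25 fragments on model metabolites", {
  panel <- defaultFragmentPanel()
  m <- defaultCCMNetwork()
  expect_equal(nrow(panel), 25)
  expect_true(all(panel$metabolite %in% m@metabolites$name))
  sim <- simulateSFLs(m, referenceFluxes(0), substrateLabeling(), panel)
  expect_equal(nrow(sim), 25)
  expect_true(all(is.finite(sim$sfl)))
})
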