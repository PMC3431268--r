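# network model: parsing, validation, stoichiometry, free-flux algebra

test_that("toy chain parses into a validated model with one balanced pool", {
  m <- loadNetwork(toyChainPath())
  expect_s4_class(m, "NetworkModel")
  expect_length(m@reactions, 3)
  expect_equal(sum(m@metabolites$role == "balanced"), 1)
  S <- stoichiometricMatrix(m)
  expect_equal(dim(S), c(1L, 3L))
  expect_equal(unname(S["B", ]), c(1, -1, -1))
})

test_that("atom-map violations raise named errors identifying the reaction", {
  bad <- writeToyNetwork(
    c("A.ext\t2\tsubstrate", "B\t2\tbalanced", "C.ext\t2\texternal"),
    c("up\tA.ext --> B\tab : ab\tno\tc\t-",
      "dup\tB --> C.ext\tab : aa\tno\te\t-"))
  expect_error(loadNetwork(bad), class = "emufluxBijectionError")
  expect_error(loadNetwork(bad), "dup")

  mismatch <- writeToyNetwork(
    c("A.ext\t2\tsubstrate", "B\t3\tbalanced", "C.ext\t3\texternal"),
    c("up\tA.ext --> B\tab : ab\tno\tc\t-",
      "out\tB --> C.ext\tabc : abc\tno\te\t-"))
  expect_error(loadNetwork(mismatch), class = "emufluxCarbonMismatch")

  dupid <- writeToyNetwork(
    c("A.ext\t2\tsubstrate", "B\t2\tbalanced", "C.ext\t2\texternal"),
    c("up\tA.ext --> B\tab : ab\tno\tc\t-",
      "up\tB --> C.ext\tab : ab\tno\te\t-"))
  expect_error(loadNetwork(dupid), class = "emufluxDuplicateReaction")

  orphan <- writeToyNetwork(
    c("A.ext\t2\tsubstrate", "B\t2\tbalanced", "O\t2\tbalanced",
      "C.ext\t2\texternal"),
    c("up\tA.ext --> B\tab : ab\tno\tc\t-",
      "out\tB --> C.ext\tab : ab\tno\te\t-",
      "mk\tB --> O\tab : ab\tno\tc\t-"))
  expect_error(loadNetwork(orphan), class = "emufluxOrphanMetabolite")
})

test_that("the packaged fermentative CCM network has the expected shape", {
  m <- defaultCCMNetwork()
  expect_length(m@reactions, 60)
  key <- c("pgi", "zwf", "gnd", "tkl1", "tkl2", "tal", "pdc", "pyc",
           "oaa_tm", "ald6", "acs", "etoh_out", "glyc_out", "ace_out",
           "succ_out", "carb_bm", "lip_bm", "bdh")
  expect_true(all(key %in% reactionIds(m)))
  S <- stoichiometricMatrix(m)
  expect_equal(nrow(S), sum(m@metabolites$role == "balanced"))
  # degrees of freedom = reactions - rank = number of default free fluxes + 1
  expect_equal(ncol(S) - qr(S)$rank, length(defaultFreeFluxes()) + 1L)
  # carbon conservation: every fully mapped reaction moves each reactant
  # carbon to exactly one product carbon
  carbonsOf <- setNames(m@metabolites$carbons, m@metabolites$name)
  for (r in m@reactions) {
    if (is.null(r$pmap)) next
    nReact <- sum(carbonsOf[r$reactants])
    nProd <- sum(vapply(r$pmap, ncol, 0L))
    expect_equal(nProd, nReact, info = r$id)
  }
})

test_that("reported pathway fluxes close the nodes they fully cover", {
  tab <- referenceFluxTable()
  v <- function(rxn, col) tab[tab$reaction == rxn, col]
  # G6P node: uptake 100 = glycolysis + oxidative PPP + carbohydrate drain
  expect_lt(abs(100 - v("pgi", "a300") - v("zwf", "a300") -
                  v("carb_bm", "a300")), 0.5)
  for (col in c("a0", "a300")) {
    # acetaldehyde node: PDC = ethanol + acetaldehyde dehydrogenase
    expect_lt(abs(v("pdc", col) - v("etoh_out", col) - v("ald6", col)), 0.5)
    # acetate node: ALD6 = acetate excretion + acetyl-CoA synthetase
    expect_lt(abs(v("ald6", col) - v("ace_out", col) - v("acs", col)), 0.5)
  }
})

test_that("validateFluxBalance reports residuals and localizes perturbations", {
  m <- loadNetwork(toySplitPath())
  fl <- toySplitFlux()
  rep0 <- validateFluxBalance(m, fl)
  expect_lt(rep0$maxAbsResidual, 1e-12)
  expect_length(rep0$irreversibilityViolations, 0)
  v <- fl@net; v[["r2"]] <- v[["r2"]] + 1
  rep1 <- validateFluxBalance(m, v)
  res <- setNames(rep1$residuals$residual, rep1$residuals$metabolite)
  expect_equal(unname(res[["A"]]), -1)
  expect_equal(unname(res[["X"]]), +1)
  expect_equal(unname(res[["Y"]]), 0)
})

test_that("free-flux reconstruction solves the balances exactly", {
  m <- defaultCCMNetwork()
  p <- freeFluxParam(m, defaultFreeFluxes())
  fl0 <- referenceFluxes(0)
  v <- fluxFromFree(p, fl0@net[defaultFreeFluxes()])
  expect_lt(max(abs(v@net[names(fl0@net)] - fl0@net)), 1e-9)
  # PPP split fixed by the free drains: glycolysis gets the G6P remainder
  expect_equal(unname(v@net[["pgi"]]),
               100 - v@net[["zwf"]] - v@net[["carb_bm"]], tolerance = 1e-9)
  S <- stoichiometricMatrix(m)
  # property: random free-flux draws stay balanced
  set.seed(42)
  for (i in 1:20) {
    vals <- runif(length(defaultFreeFluxes()), 0, 50)
    vi <- fluxFromFree(p, vals)
    expect_lt(max(abs(S %*% vi@net)) / max(1, max(abs(vi@net))), 1e-9)
  }
})

test_that("free-flux map is linear and supports full determination", {
  m <- loadNetwork(toySplitPath())
  # fully determined: all DOF fixed or free
  S <- stoichiometricMatrix(m)
  free <- c("r1", "r2", "r4")
  p <- freeFluxParam(m, free, fixed = c(up = 100))
  v1 <- fluxFromFree(p, c(40, 30, 25))
  expect_equal(unname(v1@net[["r3"]]), 30, tolerance = 1e-10)
  expect_equal(unname(v1@net[["xout"]]), 95, tolerance = 1e-10)
  # linearity: doubling frees and the uptake doubles everything
  v2 <- fluxFromFree(p, 2 * c(40, 30, 25), fixed = c(up = 200))
  expect_equal(unname(v2@net), unname(2 * v1@net), tolerance = 1e-10)
  # an inconsistent free set (not a basis) raises a named error
  expect_error(freeFluxParam(m, c("r1", "r2")), class = "emufluxBasisError")
})

test_that("normalization invariance: scaling preserves zero residuals", {
  m <- loadNetwork(toySplitPath())
  fl <- toySplitFlux()
  for (s in c(0.5, 2, 7)) {
    rep <- validateFluxBalance(m, fl@net * s)
    expect_lt(rep$maxAbsResidual, 1e-10)
  }
})

test_that("the network file format round-trips the packaged model", {
  m <- defaultCCMNetwork()
  path <- tempfile(fileext = ".tsv")
  writeNetwork(m, path)
  m2 <- loadNetwork(path)
  expect_equal(reactionIds(m2), reactionIds(m))
  expect_equal(m2@metabolites, m@metabolites)
  for (id in reactionIds(m)) {
    a <- m@reactions[[id]]; b <- m2@reactions[[id]]
    expect_equal(b$reactants, a$reactants, info = id)
    expect_equal(b$products, a$products, info = id)
    expect_equal(b$pmap, a$pmap, info = id)
    expect_equal(b$reversible, a$reversible, info = id)
    expect_equal(b$cofactors, a$cofactors, info = id)
  }
})
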