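# Toy atom-mapped networks built in code (written through the package's own
# file dialect so the parser is exercised everywhere).

writeToyNetwork <- function(metabolites, reactions) {
  path <- tempfile(fileext = ".tsv")
  con <- file(path, "w")
  writeLines("@metabolites", con)
  writeLines(metabolites, con)
  writeLines("@reactions", con)
  writeLines(reactions, con)
  close(con)
  path
}

# A.ext(2C) -> B -> two external sinks; single balanced metabolite B
toyChainPath <- function() {
  writeToyNetwork(
    c("A.ext\t2\tsubstrate", "B\t2\tbalanced",
      "C.ext\t2\texternal", "D.ext\t2\texternal"),
    c("up\tA.ext --> B\tab : ab\tno\tc\t-",
      "toC\tB --> C.ext\tab : ab\tno\te\t-",
      "toD\tB --> D.ext\tab : ab\tno\te\t-"))
}

# split / recombine network with a decarboxylating branch and a reversible
# isomerase; used against the brute-force positional-isotopomer oracle
toySplitPath <- function() {
  writeToyNetwork(
    c("S.ext\t3\tsubstrate", "A\t3\tbalanced", "X\t3\tbalanced",
      "Y\t2\tbalanced", "W\t1\tbalanced", "X.ext\t3\texternal",
      "Y.ext\t2\texternal", "W.ext\t1\texternal"),
    c("up\tS.ext --> A\tabc : abc\tno\tc\t-",
      "r1\tA --> X\tabc : abc\tyes\tc\t-",
      "r2\tA --> X\tabc : bca\tno\tc\t-",
      "r3\tA --> Y + W\tabc : bc + a\tno\tc\t-",
      "r4\tY + W --> X\tab + c : cab\tno\tc\t-",
      "wout\tW --> W.ext\ta : a\tno\te\t-",
      "yout\tY --> Y.ext\tab : ab\tno\te\t-",
      "xout\tX --> X.ext\tabc : abc\tno\te\t-"))
}

toySplitFlux <- function(r1 = 40, r2 = 30, r3 = 30, r4 = 25, x1 = 0.2) {
  # W and Y balances: r3 = r4 + drain; X: r1 + r2 + r4 = xout
  fluxVector(c(up = r1 + r2 + r3, r1 = r1, r2 = r2, r3 = r3, r4 = r4,
               wout = r3 - r4, yout = r3 - r4, xout = r1 + r2 + r4),
             exchange = c(r1 = x1))
}

toySplitTargets <- function() {
  data.frame(fragment = c("X_full", "X_12", "Y_full"),
             metabolite = c("X", "X", "Y"),
             positions = c("1,2,3", "1,2", "1,2"),
             moiety = "", family = "none")
}
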