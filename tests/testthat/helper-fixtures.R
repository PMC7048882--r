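# Shared fixtures and independent oracles for the test suite. Everything is
# built in code; the only file fixture is the published probability-snapshot
# CSV shipped in extdata.

anxietySnapshots <- function() {
  readSnapshots(system.file("extdata", "anxiety_worry_snapshots.csv",
                            package = "tscoremap"))
}

# fitted published anxiety item, computed once per test run
.fixtureCache <- new.env(parent = emptyenv())
fittedAnxietyItem <- function() {
  if (is.null(.fixtureCache$anx))
    .fixtureCache$anx <- fitItemFromSnapshots(
      anxietySnapshots(), itemId = "anx_worry",
      labels = c("never", "rarely", "sometimes", "often", "always"))
  .fixtureCache$anx
}

dichotomousItem <- function(a = 1, b = 0)
  ItemParameters("dich", c("no", "yes"), slope = a, thresholds = b)

threeCatItem <- function(a = 2, b = c(-1, 1))
  ItemParameters("tri", c("low", "mid", "high"), slope = a, thresholds = b)

# brute-force summed-score distribution by exhaustive pattern enumeration
enumSummedDist <- function(bank, theta) {
  Ks <- vapply(bankItems(bank), nCategories, integer(1))
  patterns <- as.matrix(expand.grid(lapply(Ks, seq_len)))
  probs <- rep(1, nrow(patterns))
  items <- bankItems(bank)
  for (j in seq_along(items)) {
    p <- categoryProbabilities(items[[j]], theta)
    probs <- probs * p[patterns[, j]]
  }
  s <- rowSums(patterns)
  out <- tapply(probs, s, sum)
  out <- out[order(as.integer(names(out)))]
  stats::setNames(as.numeric(out), names(out))
}

# midranks computed by explicit position averaging (independent of rank())
bruteMidrank <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  pos <- 1L
  while (pos <= length(x)) {
    same <- which(x[ord] == x[ord[pos]])
    r[ord[same]] <- mean(same)
    pos <- max(same) + 1L
  }
  r
}
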