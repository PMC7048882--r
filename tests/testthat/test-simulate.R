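test_that("fixture banks are reproducible and well-formed", {
  b1 <- makeFixtureBank(nItems = 8, K = 5, seed = 3)
  b2 <- makeFixtureBank(nItems = 8, K = 5, seed = 3)
  tmp <- withr::local_tempdir()
  writeBank(b1, file.path(tmp, "b1.json"))
  writeBank(b2, file.path(tmp, "b2.json"))
  expect_identical(readLines(file.path(tmp, "b1.json")),
                   readLines(file.path(tmp, "b2.json")))
  expect_false(identical(
    itemSlope(makeFixtureBank(8, 5, seed = 4)[[1]]), itemSlope(b1[[1]])))
  expect_equal(nItems(b1), 8L)
  for (item in bankItems(b1)) {
    expect_equal(nCategories(item), 5L)
    expect_length(itemThresholds(item), 4L)
    expect_true(all(diff(itemThresholds(item)) > 0))
  }
  expect_error(makeFixtureBank(4, 5, slopeRange = c(-1, 2)), "degenerate")
  expect_error(makeFixtureBank(4, 5, thresholdSpan = c(2, -2)), "degenerate")
})

test_that("the engineered item's squeezed category is never modal", {
  bank <- makeFixtureBank(nItems = 4, K = 5, seed = 2)
  nm <- bank[[nItems(bank)]]
  mc <- modalCategory(nm, thetaFromT(seq(20, 80, by = 0.001)))
  expect_false(2L %in% mc)
  # and without the flag, no item is engineered
  plain <- makeFixtureBank(nItems = 4, K = 5, seed = 2,
                           includeNeverModal = FALSE)
  expect_false(grepl("never-modal", plain[[4]]@stem))
})

test_that("simulated category frequencies converge to model probabilities", {
  item <- threeCatItem()
  bank <- ItemBank("one", list(item), center = 50, scale = 10)
  # theta fixed at 0 by a degenerate latent distribution
  sim <- simulateRespondents(bank, n = 100000, thetaMeanT = 50,
                             thetaSdT = 1e-9, seed = 31)
  p <- categoryProbabilities(item, 0)
  emp <- tabulate(sim$responses$tri, 3) / 100000
  expect_true(all(abs(emp - p) < 3 * sqrt(p * (1 - p) / 100000)))
})

test_that("simulation respects seed and missing-rate contracts", {
  bank <- makeFixtureBank(nItems = 4, K = 5, seed = 2)
  s1 <- simulateRespondents(bank, n = 50, seed = 7)
  s2 <- simulateRespondents(bank, n = 50, seed = 7)
  s3 <- simulateRespondents(bank, n = 50, seed = 8)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$responses, s3$responses))
  expect_false(anyNA(s1$responses))
  withMiss <- simulateRespondents(bank, n = 400, missingRate = 0.1,
                                  seed = 7)
  nmiss <- sum(is.na(as.matrix(withMiss$responses[, -1])))
  expect_gt(nmiss, 0)
  expect_lt(abs(nmiss / (400 * 4) - 0.1), 3 * sqrt(0.1 * 0.9 / 1600))
  expect_equal(attr(withMiss, "config")$seed, 7)
  # simulation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulateRespondents(bank, n = 5, seed = 1))
  expect_identical(runif(1), before)
})

test_that("expected match rate for one item equals hand enumeration", {
  item <- threeCatItem()
  bank <- ItemBank("one", list(item))
  map <- buildMap(bank)
  grid <- makeGrid()
  em <- expectedMatchRates(bank, map, popGrid = grid)
  # hand enumeration over the 3 response patterns: score each, read the
  # predicted band, accumulate model-probability-weighted indicators
  tab <- scoreTable(summedScoreToT(bank, grid))
  hand <- 0
  for (x in 1:3) {
    tx <- tab$t[tab$summed_score == x]
    pred <- unname(predictResponses(min(max(tx, 20), 80 - 1e-9), map)[[1]])
    px <- categoryProbabilities(item, quadNodes(grid))[, x]
    hand <- hand + sum(quadWeights(grid) * px) * (pred == x)
  }
  expect_equal(unname(em$perItem), hand, tolerance = 1e-12)
  expect_equal(em$scale, hand, tolerance = 1e-12)
  expect_equal(em$method, "enumeration")
})

test_that("a near-deterministic item is matched almost surely", {
  sharp <- ItemParameters("sharp", paste0("c", 1:3), slope = 50,
                          thresholds = c(-0.8, 0.8))
  bank <- ItemBank("sharp", list(sharp))
  em <- expectedMatchRates(bank, buildMap(bank))
  expect_gt(unname(em$perItem), 0.99)
})

test_that("Monte Carlo match rates agree with exact enumeration", {
  bank <- makeFixtureBank(nItems = 4, K = 5, seed = 2)
  map <- buildMap(bank)
  exact <- expectedMatchRates(bank, map)
  mc <- expectedMatchRates(bank, map, enumerate = FALSE,
                           nMonteCarlo = 200000, seed = 17)
  expect_equal(mc$method, "montecarlo")
  se <- sqrt(exact$perItem * (1 - exact$perItem) / 200000)
  expect_true(all(abs(mc$perItem - exact$perItem) < 3 * se))
  seScale <- sqrt(exact$scale * (1 - exact$scale) / 200000)
  expect_lt(abs(mc$scale - exact$scale), 3 * seScale)
})

test_that("full pipeline on simulated data recovers the oracle rates", {
  bank <- makeFixtureBank(nItems = 4, K = 5, seed = 2)
  map <- buildMap(bank)
  pop <- makeGrid(nNodes = 161, range = c(0.2 - 4 * 0.95, 0.2 + 4 * 0.95),
                  mean = 0.2, sd = 0.95)
  em <- expectedMatchRates(bank, map, popGrid = pop)
  for (seed in c(7, 11, 13)) {
    sim <- simulateRespondents(bank, n = 1500, seed = seed)
    rep <- validationReport(sim$responses, bank, map)
    st <- reportItemStats(rep)
    obs <- st$exact_pct[match(names(em$perItem), st$item_id)] / 100
    se <- sqrt(em$perItem * (1 - em$perItem) / st$n)
    expect_true(all(abs(obs - em$perItem) < 3 * se),
                info = paste("seed", seed))
  }
})

test_that("observed-predicted Spearman is strong on clinical-like data", {
  # the clinical-like emulation bank: fitted published item + companions
  # with operational-magnitude discriminations and spread thresholds
  bank <- makeClinicalBank()
  expect_equal(nItems(bank), 4L)
  expect_true(all(vapply(bankItems(bank), itemSlope, numeric(1)) >= 1.5))
  map <- buildMap(bank)
  sim <- simulateRespondents(bank, n = 1500, seed = 7)
  rep <- validationReport(sim$responses, bank, map)
  expect_true(all(reportItemStats(rep)$spearman_r > 0.7))
})
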