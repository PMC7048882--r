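test_that("quadrature grid is symmetric and normalized", {
  g <- makeGrid()
  expect_length(quadNodes(g), 81L)
  expect_equal(sum(quadWeights(g)), 1, tolerance = 1e-12)
  expect_equal(quadWeights(g), rev(quadWeights(g)))
  expect_equal(sum(quadNodes(g) * quadWeights(g)), 0, tolerance = 1e-12)
  expect_error(makeGrid(2), "nNodes")
  expect_error(makeGrid(range = c(2, -2)), "range")
})

test_that("summed-score recursion matches binomial and base cases", {
  twoDich <- ItemBank("b2", list(ItemParameters("i1", c("a", "b"), 1, 0),
                                 ItemParameters("i2", c("a", "b"), 1, 0)))
  d <- lwSummedDistribution(twoDich, 0)
  expect_equal(names(d), c("2", "3", "4"))
  expect_equal(unname(d), c(0.25, 0.5, 0.25))
  # single item: distribution is the category probability vector
  one <- ItemBank("b1", list(threeCatItem()))
  expect_equal(unname(lwSummedDistribution(one, 0.3)),
               unname(categoryProbabilities(threeCatItem(), 0.3)))
})

test_that("summed-score recursion equals exhaustive enumeration", {
  for (seed in c(2, 9)) {
    bank <- makeFixtureBank(nItems = 4, K = 5, seed = seed)
    for (th in c(-1.3, 0, 0.7)) {
      lw <- lwSummedDistribution(bank, th)
      en <- enumSummedDist(bank, th)
      expect_equal(unname(lw), unname(en), tolerance = 1e-12)
      expect_equal(sum(lw), 1, tolerance = 1e-12)
    }
  }
  # mixed category counts
  mixed <- ItemBank("mx", list(dichotomousItem(1.5, -0.4),
                               threeCatItem(),
                               ItemParameters("q", paste0("c", 1:4), 2,
                                              c(-1, 0, 1))))
  expect_equal(unname(lwSummedDistribution(mixed, 0.7)),
               unname(enumSummedDist(mixed, 0.7)), tolerance = 1e-12)
})

test_that("summed-score-to-T table is monotone, symmetric and dense-grid accurate", {
  # a symmetric bank maps its middle summed score to T = 50
  sym <- ItemBank("sym", list(
    ItemParameters("s1", paste0("c", 1:3), 1.8, c(-0.8, 0.8)),
    ItemParameters("s2", paste0("c", 1:3), 1.8, c(-0.8, 0.8))))
  tb <- scoreTable(summedScoreToT(sym))
  expect_equal(tb$t[tb$summed_score == 4], 50, tolerance = 0.01)
  for (seed in c(2, 9)) {
    bank <- makeFixtureBank(nItems = 4, K = 5, seed = seed)
    tb <- scoreTable(summedScoreToT(bank))
    expect_equal(tb$summed_score, 4:20)
    expect_false(is.unsorted(tb$theta_eap, strictly = TRUE))
    # dense-grid oracle: 10001 nodes
    dense <- scoreTable(summedScoreToT(bank, makeGrid(10001)))
    expect_lt(max(abs(tb$theta_eap - dense$theta_eap)), 0.005)
  }
})

test_that("pattern EAP contracts the prior and respects directionality", {
  bank <- makeFixtureBank(nItems = 4, K = 5, seed = 2)
  expect_error(eapThetaPattern(rep(NA, 4), bank), "unscorable")
  one <- eapThetaPattern(c(3, NA, NA, NA), bank)
  expect_true(is.finite(one$theta))
  expect_lt(one$sd, 1)                 # posterior narrower than N(0,1) prior
  expect_equal(one$nAnswered, 1L)
  lo <- eapThetaPattern(rep(1, 4), bank)
  hi <- eapThetaPattern(rep(5, 4), bank)
  expect_lt(lo$theta, 0)
  expect_gt(hi$theta, 0)
  # named responses align by item id
  byName <- eapThetaPattern(c(item03 = 2, item01 = 4), bank)
  byPos <- eapThetaPattern(c(4, NA, 2, NA), bank)
  expect_equal(byName$theta, byPos$theta)
})

test_that("pattern EAP and summed-score T agree over all complete patterns", {
  # similarly discriminating items, as in operational short forms; with
  # strongly heterogeneous slopes the summed score loses information and
  # the two routes genuinely diverge
  bank <- makeFixtureBank(nItems = 4, K = 5, seed = 2,
                          slopeRange = c(2, 3.5),
                          includeNeverModal = FALSE)
  patterns <- as.matrix(expand.grid(rep(list(1:5), 4)))
  colnames(patterns) <- itemIds(bank)
  grid <- makeGrid()
  tb <- scoreTable(summedScoreToT(bank, grid))
  tSummed <- tb$t[match(rowSums(patterns), tb$summed_score)]
  resp <- data.frame(respondent_id = seq_len(nrow(patterns)), patterns)
  tPattern <- scoreResponses(resp, bank, method = "pattern", grid = grid)$t
  # weight each pattern by its model probability under the N(0,1) prior
  w <- as.vector(quadWeights(grid) %*%
                 tscoremap:::patternLikelihood(patterns, bank,
                                               quadNodes(grid)))
  wc <- stats::cov.wt(cbind(tSummed, tPattern), wt = w, cor = TRUE)
  expect_gt(wc$cor[1, 2], 0.99)
})

test_that("simulated latent traits are recovered by pattern EAP", {
  bank <- makeFixtureBank(nItems = 8, K = 5, seed = 11)
  sim <- simulateRespondents(bank, n = 2000, thetaMeanT = 50,
                             thetaSdT = 10, seed = 5)
  est <- scoreResponses(sim$responses, bank, method = "pattern")
  expect_gte(stats::cor(sim$truth$theta, est$theta), 0.90)
  expect_lte(abs(mean(est$theta - sim$truth$theta)), 0.05)
})

test_that("summed scoring falls back to pattern EAP on incomplete forms", {
  bank <- makeFixtureBank(nItems = 4, K = 5, seed = 2)
  resp <- data.frame(respondent_id = c("a", "b"),
                     item01 = c(2L, 3L), item02 = c(3L, NA),
                     item03 = c(2L, 2L), item04 = c(4L, 4L))
  expect_warning(sc <- scoreResponses(resp, bank), "incomplete")
  expect_equal(sc$method, c("summed", "pattern"))
  expect_true(all(is.finite(sc$t)))
})
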