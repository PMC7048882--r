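test_that("predictions follow the half-open band convention", {
  bank <- ItemBank("anx", list(fittedAnxietyItem()))
  map <- buildMap(bank)
  # published worked example: T = 60 predicts "rarely" (category 2)
  expect_equal(unname(predictResponses(60, map)["anx_worry"]), 2L)
  expect_equal(unname(predictResponses(61, map)["anx_worry"]), 3L)
  # a score exactly at a crossing belongs to the lower-category band
  cp <- mapBands(map)$t_low[mapBands(map)$category == 3]
  expect_equal(unname(predictResponses(cp - 1e-9, map)[[1]]), 2L)
  expect_equal(unname(predictResponses(cp, map)[[1]]), 3L)
  # range start predicts the lowest band's category; outside range clamps
  expect_equal(unname(predictResponses(20, map)[[1]]), 1L)
  expect_warning(p <- predictResponses(c(10, 95), map), "clamped")
  expect_equal(unname(p[, 1]), c(1L, 5L))
})

test_that("difference scores follow the observed-minus-predicted convention", {
  rec <- data.frame(respondent_id = c("a", "b", "c"),
                    item_id = "it", predicted = c(2L, 2L, 2L),
                    observed = c(3L, 1L, 2L))
  rec$difference <- rec$observed - rec$predicted
  expect_equal(rec$difference, c(1L, -1L, 0L))
  tb <- differenceTable(rec, "it", K = 5)
  expect_equal(tb$difference, -4:4)
  expect_equal(sum(tb$n), 3L)
  expect_equal(tb$n[tb$difference == 1], 1L)
  expect_equal(sum(tb$percent), 100)
  # all-match records put 100% at difference 0
  recs0 <- data.frame(respondent_id = 1:4, item_id = "it",
                      predicted = c(1L, 2L, 3L, 4L),
                      observed = c(1L, 2L, 3L, 4L))
  tb0 <- differenceTable(recs0, "it", K = 5)
  expect_equal(tb0$percent[tb0$difference == 0], 100)
  # missing observations are excluded from N
  recNA <- rbind(rec, data.frame(respondent_id = "d", item_id = "it",
                                 predicted = 2L, observed = NA_integer_,
                                 difference = NA_integer_))
  expect_equal(sum(differenceTable(recNA, "it", K = 5)$n), 3L)
  expect_error(differenceTable(rec, "nope"), "no scorable")
})

test_that("Spearman uses midranks and flags undefined cases", {
  mkrec <- function(p, o) data.frame(respondent_id = seq_along(p),
                                     item_id = "it", predicted = p,
                                     observed = o)
  expect_equal(spearmanPredictedObserved(mkrec(1:5, 1:5)), 1)
  expect_equal(spearmanPredictedObserved(mkrec(1:5, 5:1)), -1)
  # tied data: compare with a midrank Pearson oracle built by position
  # averaging, independent of rank()
  p <- c(1, 1, 2, 2, 3); o <- c(1, 2, 2, 2, 3)
  oracle <- stats::cor(bruteMidrank(p), bruteMidrank(o))
  expect_equal(spearmanPredictedObserved(mkrec(p, o)), oracle,
               tolerance = 1e-12)
  expect_error(spearmanPredictedObserved(mkrec(1:2, 1:2)), "at least 3")
  expect_warning(r <- spearmanPredictedObserved(mkrec(rep(2, 5), 1:5)),
                 "constant")
  expect_true(is.na(r))
})

test_that("perfect-match rate counts only fully matching complete respondents", {
  rec <- expand.grid(respondent_id = paste0("r", 1:10), item_id = c("a", "b"),
                     stringsAsFactors = FALSE)
  rec$predicted <- 2L
  rec$observed <- 2L
  expect_equal(perfectMatchRate(rec), 100)
  rec$observed[rec$respondent_id == "r3" & rec$item_id == "b"] <- 3L
  expect_equal(perfectMatchRate(rec), 90)
  # a respondent with any missing item leaves the denominator
  rec$observed[rec$respondent_id == "r7" & rec$item_id == "a"] <- NA
  expect_equal(perfectMatchRate(rec), 100 * 8 / 9)
})

test_that("the validation report is consistent and order-invariant", {
  bank <- makeFixtureBank(nItems = 4, K = 5, seed = 2)
  map <- buildMap(bank)
  sim <- simulateRespondents(bank, n = 300, missingRate = 0.03, seed = 21)
  rep <- suppressWarnings(validationReport(sim$responses, bank, map))
  st <- reportItemStats(rep)
  # per item: percentages over the difference range sum to 100
  for (id in names(reportItemTables(rep))) {
    tb <- reportItemTables(rep)[[id]]
    expect_equal(sum(tb$percent), 100, tolerance = 1e-9)
    expect_equal(sum(tb$n), st$n[st$item_id == id])
  }
  # per-item Ns reflect per-item missingness exclusion
  expect_true(all(st$n <= 300 & st$n > 250))
  ss <- reportScaleStats(rep)
  expect_lte(ss$n_complete, 300)
  expect_equal(ss$n_total, 300)
  # shuffling respondent rows leaves the report unchanged
  shuf <- sim$responses[sample.int(nrow(sim$responses)), ]
  rep2 <- suppressWarnings(validationReport(shuf, bank, map))
  expect_equal(reportItemStats(rep2), st)
  expect_equal(reportScaleStats(rep2)$perfect_match_pct,
               ss$perfect_match_pct)
})

test_that("single respondent answering the modal category matches everywhere", {
  bank <- makeFixtureBank(nItems = 4, K = 5, seed = 2)
  map <- buildMap(bank)
  # iterate scoring + prediction to a self-consistent response pattern
  resp <- rep(3L, 4)
  for (i in 1:10) {
    sc <- scoreResponses(data.frame(respondent_id = "x",
                                    t(setNames(resp, itemIds(bank)))),
                         bank)
    newResp <- unname(predictResponses(sc$t, map))
    if (all(newResp == resp)) break
    resp <- newResp
  }
  rep <- suppressWarnings(validationReport(
    data.frame(respondent_id = "x", t(setNames(resp, itemIds(bank)))),
    bank, map))
  expect_equal(reportScaleStats(rep)$perfect_match_pct, 100)
  expect_true(all(reportItemStats(rep)$exact_pct == 100))
})

test_that("schema violations are reported with the offending columns", {
  bank <- makeFixtureBank(nItems = 4, K = 5, seed = 2)
  map <- buildMap(bank)
  expect_error(validationReport(data.frame(), bank, map), "schema")
  bad <- data.frame(respondent_id = "a", item01 = 2L, itemXX = 3L)
  expect_error(validationReport(bad, bank, map), "itemXX")
  oob <- data.frame(respondent_id = "a", item01 = 6L, item02 = 1L,
                    item03 = 1L, item04 = 1L)
  expect_error(validationReport(oob, bank, map), "item01")
})
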