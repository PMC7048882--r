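# Fixture banks, GRM response simulation, and the enumeration oracle for
# expected match rates. All randomness flows through an explicit seed and a
# named generator, so outputs are reproducible across sessions.

# evaluate expr under a fixed, version-stable RNG; caller's RNG state is
# untouched
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Generate a reproducible fixture item bank
#'
#' Draws slopes uniformly from \code{slopeRange} and, per item, K-1 sorted
#' thresholds spanning \code{thresholdSpan} (with a minimum gap of 0.05 to
#' keep crossings well separated). When \code{includeNeverModal = TRUE} and
#' K >= 3, the last item is replaced by an engineered low-slope item whose
#' second category is squeezed between two near-coincident thresholds and is
#' therefore never the modal response anywhere — the map-construction edge
#' case.
#'
#' @param nItems number of items (>= 1, default 8).
#' @param K response categories per item (>= 2, default 5).
#' @param slopeRange length-2 positive range for discriminations
#'   (default c(1.2, 3)).
#' @param thresholdSpan length-2 theta interval thresholds are drawn from
#'   (default c(-2, 2)).
#' @param seed integer seed; the same seed always yields the same bank.
#' @param bankId bank identifier (default encodes the seed).
#' @param includeNeverModal engineer a never-modal-category item (default
#'   TRUE when K >= 3).
#' @return An \linkS4class{ItemBank}.
#' @export
makeFixtureBank <- function(nItems = 8, K = 5, slopeRange = c(1.2, 3),
                            thresholdSpan = c(-2, 2), seed = 1,
                            bankId = sprintf("fixture_s%d", seed),
                            includeNeverModal = K >= 3) {
  stopifnot(nItems >= 1, K >= 2)
  if (!(slopeRange[1] > 0 && slopeRange[1] <= slopeRange[2]))
    stop("degenerate slopeRange: need 0 < low <= high")
  if (!(thresholdSpan[1] < thresholdSpan[2]))
    stop("degenerate thresholdSpan")
  if (includeNeverModal && K < 3)
    stop("a never-modal category requires K >= 3")
  withSeed(seed, {
    items <- lapply(seq_len(nItems), function(j) {
      a <- stats::runif(1, slopeRange[1], slopeRange[2])
      b <- sort(stats::runif(K - 1, thresholdSpan[1], thresholdSpan[2]))
      b <- b + cumsum(c(0, pmax(0, 0.05 - diff(b))))
      ItemParameters(sprintf("item%02d", j), paste0("cat", seq_len(K)),
                     slope = a, thresholds = b,
                     stem = sprintf("Fixture item %d", j))
    })
    if (includeNeverModal) {
      # two near-coincident low thresholds squeeze category 2 out of
      # modality; remaining thresholds sit well above
      b <- c(-0.1, 0.1, if (K > 3) seq(1.5, by = 0.2, length.out = K - 3))
      items[[nItems]] <- ItemParameters(
        sprintf("item%02d", nItems), paste0("cat", seq_len(K)),
        slope = 0.8, thresholds = b,
        stem = sprintf("Fixture item %d (never-modal category 2)", nItems),
        directionNote = "engineered: category 2 is never modal")
    }
    ItemBank(bankId, items)
  })
}

#' Clinical-like emulation bank (synthetic anxiety short form)
#'
#' A deterministic four-item bank emulating an anxiety short form as
#' administered in a chronic-conditions clinical sample. The first item is
#' fitted at call time from the published probability snapshots shipped
#' with the package; the other three are synthetic companions with
#' discriminations and severity-skewed thresholds of the magnitude typical
#' of operational PROMIS calibrations (slopes around 2.5-3.7, thresholds
#' spread roughly one theta unit apart starting near the population
#' centre). This is an emulation for testing the pipeline end to end, not
#' a replication of any published calibration.
#'
#' @return An \linkS4class{ItemBank} of four five-category items.
#' @export
makeClinicalBank <- function() {
  labels <- c("never", "rarely", "sometimes", "often", "always")
  fitted <- fitItemFromSnapshots(
    readSnapshots(system.file("extdata", "anxiety_worry_snapshots.csv",
                              package = "tscoremap")),
    itemId = "anx_worry", labels = labels,
    stem = "My worries overwhelmed me")
  ItemBank("clinical_anx_emulation", list(
    fitted,
    ItemParameters("anx_syn2", labels, slope = 2.8,
                   thresholds = c(-0.2, 0.6, 1.4, 2.3),
                   stem = "Synthetic anxiety companion item 2"),
    ItemParameters("anx_syn3", labels, slope = 3.1,
                   thresholds = c(0.1, 0.9, 1.7, 2.5),
                   stem = "Synthetic anxiety companion item 3"),
    ItemParameters("anx_syn4", labels, slope = 2.5,
                   thresholds = c(-0.4, 0.5, 1.3, 2.2),
                   stem = "Synthetic anxiety companion item 4")))
}

#' Simulate graded-response respondents
#'
#' Draws latent traits theta_i from a normal distribution specified on the
#' T metric, then each response by inverse-CDF sampling from the item's
#' category probabilities at theta_i; missing entries are injected
#' completely at random at \code{missingRate}. The defaults emulate a
#' clinical chronic-conditions sample: n = 1594 respondents with T-scores
#' centred at 52 with SD 9.5.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param n number of respondents (default 1594).
#' @param thetaMeanT,thetaSdT latent-trait distribution on the T metric
#'   (defaults 52 and 9.5).
#' @param missingRate probability in [0, 1) that any single response is
#'   missing (default 0).
#' @param seed integer seed (default 7); recorded in the output attributes.
#' @return List with \code{responses} (data.frame: respondent_id + one
#'   column per item) and \code{truth} (data.frame: respondent_id, theta,
#'   t), with the full simulation configuration in
#'   \code{attr(, "config")}.
#' @export
simulateRespondents <- function(bank, n = 1594, thetaMeanT = 52,
                                thetaSdT = 9.5, missingRate = 0,
                                seed = 7) {
  stopifnot(is(bank, "ItemBank"), n >= 1, thetaSdT > 0,
            missingRate >= 0, missingRate < 1)
  center <- metricCenter(bank); scale <- metricScale(bank)
  items <- bankItems(bank)
  out <- withSeed(seed, {
    theta <- stats::rnorm(n, (thetaMeanT - center) / scale,
                          thetaSdT / scale)
    mat <- matrix(NA_integer_, nrow = n, ncol = length(items),
                  dimnames = list(NULL, names(items)))
    for (j in seq_along(items)) {
      P <- categoryProbabilities(items[[j]], theta)
      if (!is.matrix(P)) P <- matrix(P, nrow = n)
      cp <- t(apply(P, 1L, cumsum))
      u <- stats::runif(n)
      mat[, j] <- 1L + as.integer(rowSums(u > cp[, -ncol(cp), drop = FALSE]))
    }
    if (missingRate > 0)
      mat[matrix(stats::runif(length(mat)) < missingRate,
                 nrow = n)] <- NA_integer_
    list(theta = theta, mat = mat)
  })
  rid <- sprintf("R%05d", seq_len(n))
  res <- list(
    responses = data.frame(respondent_id = rid,
                           as.data.frame(out$mat),
                           stringsAsFactors = FALSE, check.names = FALSE),
    truth = data.frame(respondent_id = rid, theta = out$theta,
                       t = tFromTheta(out$theta, center, scale),
                       stringsAsFactors = FALSE))
  attr(res, "config") <- list(bank_id = bankId(bank), n = n,
                              theta_mean_t = thetaMeanT,
                              theta_sd_t = thetaSdT,
                              missing_rate = missingRate, seed = seed)
  res
}

#' Expected match rates under the model (enumeration oracle)
#'
#' The analytic twin of the simulated predicted-versus-observed analysis:
#' for a population with latent density given by \code{popGrid}, the
#' probability that a model-generated respondent's observed response matches
#' the map-predicted response at their scored T, per item and jointly
#' across all items. For banks of up to 5 items every response pattern is
#' enumerated and the result is exact (up to quadrature); larger banks use
#' quadrature-weighted Monte Carlo with an explicit seed. Enumeration above
#' 8 items is refused and falls back to Monte Carlo.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param map a \linkS4class{TScoreMap} for the bank.
#' @param popGrid \linkS4class{QuadratureGrid} giving the population theta
#'   distribution (default standard normal on [-4, 4]).
#' @param method scoring method used to place respondents, "summed" or
#'   "pattern".
#' @param scoringGrid grid used inside the scoring step (default
#'   \code{makeGrid()}; operational scoring always uses the standard-normal
#'   prior regardless of the population).
#' @param enumerate force or forbid exhaustive enumeration (default: banks
#'   with <= 5 items).
#' @param nMonteCarlo Monte Carlo sample size for large banks (default
#'   200000).
#' @param seed Monte Carlo seed (default 1).
#' @return List with \code{perItem} (named vector of match probabilities)
#'   and \code{scale} (probability of a perfect match across all items),
#'   plus \code{method} = "enumeration" or "montecarlo".
#' @export
expectedMatchRates <- function(bank, map, popGrid = makeGrid(),
                               method = c("summed", "pattern"),
                               scoringGrid = makeGrid(),
                               enumerate = nItems(bank) <= 5,
                               nMonteCarlo = 200000, seed = 1) {
  stopifnot(is(bank, "ItemBank"), is(map, "TScoreMap"),
            is(popGrid, "QuadratureGrid"))
  method <- match.arg(method)
  if (enumerate && nItems(bank) > 8L) {
    warning("full enumeration refused for banks with > 8 items; ",
            "falling back to seeded Monte Carlo")
    enumerate <- FALSE
  }
  ids <- itemIds(bank)
  Ks <- vapply(bankItems(bank), nCategories, integer(1))
  center <- metricCenter(bank); scale <- metricScale(bank)
  if (enumerate) {
    patterns <- as.matrix(expand.grid(lapply(Ks, seq_len)))
    colnames(patterns) <- ids
    tPat <- patternT(patterns, bank, method, scoringGrid)
    pred <- predictResponses(pmin(pmax(tPat, map@tMin),
                                  map@tMax - 1e-9), map)
    lik <- patternLikelihood(patterns, bank, quadNodes(popGrid))
    margP <- as.vector(quadWeights(popGrid) %*% lik)  # P(pattern)
    match <- pred[, ids, drop = FALSE] == patterns[, ids, drop = FALSE]
    perItem <- as.vector(margP %*% match)
    names(perItem) <- ids
    list(perItem = perItem,
         scale = sum(margP * (rowSums(match) == length(ids))),
         method = "enumeration")
  } else {
    nodes <- quadNodes(popGrid); w <- quadWeights(popGrid)
    res <- withSeed(seed, {
      qi <- sample.int(length(nodes), nMonteCarlo, replace = TRUE, prob = w)
      theta <- nodes[qi]
      mat <- matrix(NA_integer_, nrow = nMonteCarlo, ncol = length(ids),
                    dimnames = list(NULL, ids))
      for (j in seq_along(ids)) {
        P <- categoryProbabilities(bankItems(bank)[[j]], theta)
        cp <- t(apply(P, 1L, cumsum))
        u <- stats::runif(nMonteCarlo)
        mat[, j] <- 1L +
          as.integer(rowSums(u > cp[, -ncol(cp), drop = FALSE]))
      }
      mat
    })
    tPat <- patternT(res, bank, method, scoringGrid)
    pred <- predictResponses(pmin(pmax(tPat, map@tMin),
                                  map@tMax - 1e-9), map)
    match <- pred[, ids, drop = FALSE] == res[, ids, drop = FALSE]
    perItem <- colMeans(match)
    names(perItem) <- ids
    list(perItem = perItem, scale = mean(rowSums(match) == length(ids)),
         method = "montecarlo")
  }
}

# T-score for each (complete) pattern row under the chosen scoring method
patternT <- function(patterns, bank, method, grid) {
  center <- metricCenter(bank); scale <- metricScale(bank)
  if (method == "summed") {
    tab <- scoreTable(summedScoreToT(bank, grid))
    s <- rowSums(patterns)
    tab$t[match(s, tab$summed_score)]
  } else {
    lik <- patternLikelihood(patterns, bank, quadNodes(grid))
    post <- lik * quadWeights(grid)
    tFromTheta(colSums(post * quadNodes(grid)) / colSums(post),
               center, scale)
  }
}
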