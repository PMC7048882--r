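# Predicted-versus-observed validation: map-predicted responses at each
# respondent's scored T, difference-score tables, Spearman correlations,
# match rates.

#' Map-predicted response categories at a T-score
#'
#' Reads, for each item, the category of the map band containing the given
#' T (half-open bands: a score exactly at a band boundary belongs to the
#' lower-category band). Scores outside the map range are clamped to the
#' nearest band, with a warning.
#'
#' @param t numeric vector of T-scores.
#' @param map a \linkS4class{TScoreMap}.
#' @return For scalar t, a named integer vector (one predicted category per
#'   item); for vector t, a length(t) x nItems integer matrix.
#' @export
predictResponses <- function(t, map) {
  stopifnot(is(map, "TScoreMap"), is.numeric(t), all(is.finite(t)))
  if (any(t < map@tMin | t >= map@tMax)) {
    warning(sum(t < map@tMin | t >= map@tMax),
            " T-score(s) outside [", map@tMin, ", ", map@tMax,
            ") clamped to the nearest band")
    t <- pmin(pmax(t, map@tMin), map@tMax - 1e-9)
  }
  b <- mapBands(map)
  ids <- unique(b$item_id)
  out <- matrix(NA_integer_, nrow = length(t), ncol = length(ids),
                dimnames = list(NULL, ids))
  for (id in ids) {
    bi <- b[b$item_id == id, , drop = FALSE]
    bi <- bi[order(bi$t_low), , drop = FALSE]
    out[, id] <- bi$category[findInterval(t, bi$t_low)]
  }
  if (length(t) == 1L) drop(out) else out
}

#' Difference-score distribution for one item
#'
#' Tabulates observed-minus-predicted category differences over the full
#' range -(K-1)..+(K-1). Positive differences mean the observed response was
#' more severe than the map predicted. Records with a missing observed
#' response are excluded from N.
#'
#' @param records data.frame of prediction records with columns item_id,
#'   predicted, observed (observed may be NA).
#' @param itemId the item to tabulate.
#' @param K number of categories (default: inferred from the records).
#' @return data.frame: difference, n, percent (percent of the item's
#'   scorable N).
#' @export
differenceTable <- function(records, itemId, K = NULL) {
  r <- records[records$item_id == itemId & !is.na(records$observed), ,
               drop = FALSE]
  if (nrow(r) == 0L)
    stop("no scorable records for item '", itemId, "'")
  if (is.null(K)) K <- max(r$predicted, r$observed)
  d <- r$observed - r$predicted
  vals <- seq.int(-(K - 1L), K - 1L)
  n <- vapply(vals, function(v) sum(d == v), integer(1))
  data.frame(difference = vals, n = n, percent = 100 * n / nrow(r))
}

#' Spearman correlation between predicted and observed responses
#'
#' Rank correlation with average (mid-) ranks for ties — Pearson correlation
#' of the midranks. Requires at least 3 scorable pairs; if either vector is
#' constant the correlation is undefined and NA is returned with a warning
#' rather than a silent 0.
#'
#' @inheritParams differenceTable
#' @param itemId item to correlate; NULL uses all records as given.
#' @return Correlation in [-1, 1], or NA if undefined.
#' @export
spearmanPredictedObserved <- function(records, itemId = NULL) {
  r <- if (is.null(itemId)) records
       else records[records$item_id == itemId, , drop = FALSE]
  r <- r[!is.na(r$observed), , drop = FALSE]
  if (nrow(r) < 3L)
    stop("need at least 3 scorable predicted/observed pairs")
  if (length(unique(r$predicted)) < 2L || length(unique(r$observed)) < 2L) {
    warning("constant predicted or observed vector: Spearman correlation ",
            "undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(rank(r$predicted), rank(r$observed))
}

#' Scale-level perfect-match rate
#'
#' Percentage of respondents whose observed response equals the predicted
#' response on every item of the scale. Respondents missing any item are
#' excluded from the denominator.
#'
#' @param records data.frame of prediction records with columns
#'   respondent_id, predicted, observed.
#' @return Percentage in [0, 100].
#' @export
perfectMatchRate <- function(records) {
  bad <- unique(records$respondent_id[is.na(records$observed)])
  r <- records[!(records$respondent_id %in% bad), , drop = FALSE]
  if (nrow(r) == 0L) return(NA_real_)
  agg <- tapply(r$observed == r$predicted, r$respondent_id, all)
  100 * mean(agg)
}

# report-level wrapper: undefined correlations become NA (warning) rather
# than aborting the whole report
safeSpearman <- function(records, itemId) {
  tryCatch(spearmanPredictedObserved(records, itemId),
           error = function(e) {
             warning("item ", itemId, ": Spearman undefined (",
                     conditionMessage(e), ")", call. = FALSE)
             NA_real_
           })
}

#' Run the full predicted-versus-observed validation pipeline
#'
#' Scores every respondent on the T metric, reads the map-predicted response
#' to each item at that T, and tabulates difference scores (observed minus
#' predicted), per-item exact and adjacent match percentages, per-item
#' Spearman correlations, and the scale-level perfect-match rate, together
#' with the sample's T-score mean and SD.
#'
#' @param responses data.frame: first column respondent_id, remaining
#'   columns item responses named by item id (codes 1..K, NA = missing).
#' @param bank the \linkS4class{ItemBank} the responses were collected on.
#' @param map a \linkS4class{TScoreMap} built from the same bank.
#' @param method scoring method, "summed" (default) or "pattern".
#' @param grid quadrature grid for scoring.
#' @param integerT if TRUE, predictions are read at the T rounded to the
#'   nearest integer instead of the unrounded T (compatibility option for
#'   integer-resolution published tables). Default FALSE.
#' @return A \linkS4class{ValidationReport}.
#' @export
validationReport <- function(responses, bank, map,
                             method = c("summed", "pattern"),
                             grid = makeGrid(), integerT = FALSE) {
  stopifnot(is(bank, "ItemBank"), is(map, "TScoreMap"))
  method <- match.arg(method)
  if (!is.data.frame(responses) || nrow(responses) == 0L)
    stop("schema error: responses must be a non-empty data.frame ",
         "(respondent_id + item columns)")
  unknown <- setdiff(names(responses)[-1L], itemIds(bank))
  if (length(unknown))
    stop("schema error: unknown item column(s): ",
         paste(unknown, collapse = ", "))
  scores <- scoreResponses(responses, bank, method = method, grid = grid)
  tPred <- if (integerT) round(scores$t) else scores$t
  pred <- predictResponses(tPred, map)
  if (!is.matrix(pred)) pred <- matrix(pred, nrow = 1L,
                                       dimnames = list(NULL, names(pred)))
  rm <- asResponseMatrix(responses, bank)
  ids <- itemIds(bank)
  records <- data.frame(
    respondent_id = rep(rm$ids, times = length(ids)),
    t = rep(scores$t, times = length(ids)),
    item_id = rep(ids, each = nrow(pred)),
    predicted = as.integer(pred[, ids]),
    observed = as.integer(rm$mat[, ids]),
    stringsAsFactors = FALSE)
  records$difference <- records$observed - records$predicted

  Ks <- vapply(bankItems(bank), nCategories, integer(1))
  itemTables <- list(); stats <- list()
  for (j in seq_along(ids)) {
    tb <- differenceTable(records, ids[j], K = Ks[j])
    itemTables[[ids[j]]] <- tb
    stats[[j]] <- data.frame(
      item_id = ids[j], n = sum(tb$n),
      exact_pct = tb$percent[tb$difference == 0],
      minus1_pct = tb$percent[tb$difference == -1],
      plus1_pct = tb$percent[tb$difference == 1],
      spearman_r = safeSpearman(records, ids[j]),
      stringsAsFactors = FALSE)
  }
  completeIds <- setdiff(unique(records$respondent_id),
                         records$respondent_id[is.na(records$observed)])
  agg <- if (length(completeIds)) {
    rc <- records[records$respondent_id %in% completeIds, , drop = FALSE]
    tapply(rc$difference == 0L, rc$respondent_id, all)
  } else logical(0)
  new("ValidationReport",
      bankId = bankId(bank), method = method, records = records,
      itemTables = itemTables,
      itemStats = do.call(rbind, c(stats, list(make.row.names = FALSE))),
      scaleStats = list(
        perfect_match_pct = if (length(agg)) 100 * mean(agg) else NA_real_,
        n_perfect = sum(agg), n_complete = length(agg),
        n_total = nrow(rm$mat),
        t_mean = mean(scores$t), t_sd = stats::sd(scores$t)))
}

#' Write a validation report as a tidy CSV
#'
#' One row per item and difference value, in the shape of a published
#' difference-score table: item_id, difference, n, percent, spearman_r,
#' total_n.
#'
#' @param report a \linkS4class{ValidationReport}.
#' @param file output path.
#' @return The path, invisibly.
#' @export
reportToCSV <- function(report, file) {
  stopifnot(is(report, "ValidationReport"))
  st <- reportItemStats(report)
  rows <- lapply(names(reportItemTables(report)), function(id) {
    tb <- reportItemTables(report)[[id]]
    data.frame(item_id = id, difference = tb$difference, n = tb$n,
               percent = round(tb$percent, 1),
               spearman_r = st$spearman_r[st$item_id == id],
               total_n = st$n[st$item_id == id], stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
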