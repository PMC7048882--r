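# Building T-score maps: bands of the score continuum where each response
# category is the most probable response, with bisection-refined crossings.

#' Locate the T-score where two category curves cross
#'
#' Finds, by bisection, the T at which category catB overtakes catA as the
#' more probable response. The bracket must straddle the crossing:
#' P(catA) > P(catB) at bracket[1] and P(catA) < P(catB) at bracket[2].
#' Bisection runs until the bracket is narrower than \code{tol} T units, so
#' the returned value always lies inside the original bracket.
#'
#' @param item an \linkS4class{ItemParameters} object.
#' @param catA,catB category indices (1..K).
#' @param bracket numeric length-2 T interval straddling the crossing.
#' @param center,scale the T metric (defaults 50, 10).
#' @param tol bracket width at termination (default 1e-6 T units).
#' @return The crossing T-score.
#' @examples
#' it <- ItemParameters("x", c("no", "yes"), slope = 1, thresholds = 0)
#' crossingPoint(it, 1, 2, c(20, 80))   # 50: symmetric dichotomous item
#' @export
crossingPoint <- function(item, catA, catB, bracket, center = 50,
                          scale = 10, tol = 1e-6) {
  stopifnot(is(item, "ItemParameters"), length(bracket) == 2L,
            bracket[1] < bracket[2])
  K <- nCategories(item)
  stopifnot(catA %in% seq_len(K), catB %in% seq_len(K), catA != catB)
  f <- function(t) {
    p <- categoryProbabilities(item, thetaFromT(t, center, scale))
    p[catB] - p[catA]
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  # flo == 0 means the crossing sits exactly at the lower bracket edge,
  # which the half-open band convention assigns to the lower category
  if (!(flo <= 0 && fhi > 0))
    stop("bracket [", lo, ", ", hi, "] does not straddle the ", catA, "->",
         catB, " crossing (f = ", format(flo, digits = 4), ", ",
         format(fhi, digits = 4), ")")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Build a T-score map for an item bank
#'
#' Scans the modal response category of every item on a fine T grid, refines
#' each change point by bisection, and assembles half-open bands
#' [t_low, t_high) that tile the requested range. A score exactly at a
#' crossing belongs to the lower-category band (the lower-index tie rule).
#' Categories that are never modal anywhere in the range are omitted from
#' the bands and listed in \code{omittedCategories()}.
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param tMin,tMax map range on the T metric (defaults 20, 80: +/- 3
#'   reference SD, covering PROMIS reporting ranges).
#' @param resolution grid step of the modal scan in T units (default 0.01).
#' @return A \linkS4class{TScoreMap}.
#' @examples
#' bank <- ItemBank("demo", list(
#'   ItemParameters("i1", c("no", "yes"), slope = 1, thresholds = 0)))
#' buildMap(bank)   # two bands: [20,50) and [50,80)
#' @export
buildMap <- function(bank, tMin = 20, tMax = 80, resolution = 0.01) {
  stopifnot(is(bank, "ItemBank"), tMin < tMax, resolution > 0)
  center <- metricCenter(bank); scale <- metricScale(bank)
  grid <- seq(tMin, tMax, by = resolution)
  if (grid[length(grid)] < tMax) grid <- c(grid, tMax)
  bands <- list(); omitted <- list()
  for (item in bankItems(bank)) {
    mc <- modalCategory(item, thetaFromT(grid, center, scale))
    chg <- which(diff(mc) != 0)
    cuts <- vapply(chg, function(i)
      crossingPoint(item, mc[i], mc[i + 1L], c(grid[i], grid[i + 1L]),
                    center, scale), numeric(1))
    lows <- c(tMin, cuts); highs <- c(cuts, tMax)
    cats <- mc[c(1L, chg + 1L)]
    bands[[itemId(item)]] <- data.frame(
      item_id = itemId(item), category = as.integer(cats),
      label = responseLabels(item)[cats], t_low = lows, t_high = highs,
      stringsAsFactors = FALSE)
    miss <- setdiff(seq_len(nCategories(item)), cats)
    if (length(miss))
      omitted[[itemId(item)]] <- data.frame(
        item_id = itemId(item), category = as.integer(miss),
        label = responseLabels(item)[miss], stringsAsFactors = FALSE)
  }
  emptyOmit <- data.frame(item_id = character(0), category = integer(0),
                          label = character(0), stringsAsFactors = FALSE)
  new("TScoreMap", bankId = bankId(bank), tMin = tMin, tMax = tMax,
      bands = do.call(rbind, c(bands, list(make.row.names = FALSE))),
      omitted = if (length(omitted))
        do.call(rbind, c(omitted, list(make.row.names = FALSE)))
      else emptyOmit,
      resolution = resolution)
}

#' Export a T-score map
#'
#' Writes the map as JSON (exact band endpoints, full double precision), a
#' tidy CSV (one row per band, columns bank_id, item_id, category, label,
#' t_low, t_high), or a deterministic SVG figure with a T-score ruler and
#' one shaded band row per item. JSON and CSV output is byte-stable across
#' runs; the SVG embeds no timestamps.
#'
#' @param map a \linkS4class{TScoreMap}.
#' @param file output path.
#' @param format one of "json", "csv", "svg".
#' @param digits for CSV: decimal places for band endpoints. The default
#'   (NULL) keeps full precision so that CSV round trips preserve endpoints;
#'   use 1 for published-style 0.1-T reporting.
#' @return The output path, invisibly.
#' @export
exportMap <- function(map, file, format = c("json", "csv", "svg"),
                      digits = NULL) {
  stopifnot(is(map, "TScoreMap"))
  format <- match.arg(format)
  switch(format,
    json = writeMap(map, file),
    csv = {
      b <- mapBands(map)
      out <- data.frame(bank_id = map@bankId, b, stringsAsFactors = FALSE)
      if (!is.null(digits)) {
        out$t_low <- round(out$t_low, digits)
        out$t_high <- round(out$t_high, digits)
      }
      utils::write.csv(out, file, row.names = FALSE, quote = TRUE)
    },
    svg = writeLines(mapFigureSVG(map), file)
  )
  invisible(file)
}

# Deterministic SVG: a horizontal T ruler on top, one row per item below it,
# each band a shaded rectangle labelled with its category label.
mapFigureSVG <- function(map, width = 840, rowHeight = 34) {
  b <- mapBands(map)
  ids <- unique(b$item_id)
  marginL <- 150; marginR <- 20; marginT <- 40
  plotW <- width - marginL - marginR
  height <- marginT + rowHeight * length(ids) + 30
  tx <- function(t) marginL + (t - map@tMin) / (map@tMax - map@tMin) * plotW
  fills <- c("#deebf7", "#9ecae1", "#6baed6", "#3182bd", "#08519c",
             "#08306b", "#041f4a")
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    width, height, width, height),
    '<style>text{font-family:sans-serif;font-size:11px;}</style>',
    sprintf('<line x1="%.2f" y1="%d" x2="%.2f" y2="%d" stroke="black"/>',
            tx(map@tMin), marginT - 12, tx(map@tMax), marginT - 12))
  for (tick in seq(ceiling(map@tMin / 5) * 5, floor(map@tMax / 5) * 5,
                   by = 5)) {
    out <- c(out,
      sprintf('<line x1="%.2f" y1="%d" x2="%.2f" y2="%d" stroke="black"/>',
              tx(tick), marginT - 16, tx(tick), marginT - 8),
      sprintf('<text x="%.2f" y="%d" text-anchor="middle">%d</text>',
              tx(tick), marginT - 20, tick))
  }
  for (i in seq_along(ids)) {
    bi <- b[b$item_id == ids[i], , drop = FALSE]
    y <- marginT + (i - 1) * rowHeight
    out <- c(out, sprintf(
      '<g class="item-row" data-item="%s">', esc(ids[i])),
      sprintf('<text x="%d" y="%.1f" text-anchor="end">%s</text>',
              marginL - 8, y + rowHeight * 0.62, esc(ids[i])))
    for (j in seq_len(nrow(bi))) {
      x0 <- tx(bi$t_low[j]); x1 <- tx(bi$t_high[j])
      out <- c(out,
        sprintf('<rect x="%.2f" y="%.1f" width="%.2f" height="%.1f" fill="%s" stroke="white"/>',
                x0, y + 4, x1 - x0, rowHeight - 10,
                fills[(bi$category[j] - 1) %% length(fills) + 1]),
        if (x1 - x0 > 45) sprintf(
          '<text x="%.2f" y="%.1f" text-anchor="middle" fill="%s">%s</text>',
          (x0 + x1) / 2, y + rowHeight * 0.62,
          if (bi$category[j] >= 4) "white" else "black", esc(bi$label[j])))
    }
    out <- c(out, '</g>')
  }
  c(out, '</svg>')
}
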