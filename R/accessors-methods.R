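#' @rdname ItemParameters-class
#' @export
setMethod("itemId", "ItemParameters", function(x) x@itemId)

#' @rdname ItemParameters-class
#' @export
setMethod("responseLabels", "ItemParameters", function(x) x@labels)

#' @rdname ItemParameters-class
#' @export
setMethod("itemSlope", "ItemParameters", function(x) x@slope)

#' @rdname ItemParameters-class
#' @export
setMethod("itemThresholds", "ItemParameters", function(x) x@thresholds)

#' @rdname ItemParameters-class
#' @export
setMethod("nCategories", "ItemParameters", function(x) length(x@labels))

#' @rdname ItemBank-class
#' @export
setMethod("bankId", "ItemBank", function(x) x@bankId)

#' @rdname ItemBank-class
#' @export
setMethod("bankItems", "ItemBank", function(x) {
  names(x@items) <- vapply(x@items, itemId, character(1))
  x@items
})

#' @rdname ItemBank-class
#' @export
setMethod("itemIds", "ItemBank", function(x)
  vapply(x@items, itemId, character(1)))

#' @rdname ItemBank-class
#' @export
setMethod("nItems", "ItemBank", function(x) length(x@items))

#' @rdname ItemBank-class
#' @export
setMethod("metricCenter", "ItemBank", function(x) x@center)

#' @rdname ItemBank-class
#' @export
setMethod("metricScale", "ItemBank", function(x) x@scale)

#' @rdname ItemBank-class
#' @export
setMethod("length", "ItemBank", function(x) length(x@items))

#' @rdname ItemBank-class
#' @param i index (integer position) or item id (character).
#' @param j,... unused.
#' @export
setMethod("[[", "ItemBank", function(x, i, j, ...) {
  if (is.character(i)) {
    k <- match(i, itemIds(x))
    if (is.na(k)) stop("no item with id '", i, "' in bank '", x@bankId, "'")
    i <- k
  }
  x@items[[i]]
})

#' @rdname TScoreMap-class
#' @export
setMethod("mapBands", "TScoreMap", function(x) x@bands)

#' @rdname TScoreMap-class
#' @export
setMethod("mapRange", "TScoreMap", function(x) c(x@tMin, x@tMax))

#' @rdname TScoreMap-class
#' @export
setMethod("omittedCategories", "TScoreMap", function(x) x@omitted)

#' @rdname QuadratureGrid-class
#' @export
setMethod("quadNodes", "QuadratureGrid", function(x) x@nodes)

#' @rdname QuadratureGrid-class
#' @export
setMethod("quadWeights", "QuadratureGrid", function(x) x@weights)

#' @rdname ScoreTable-class
#' @export
setMethod("scoreTable", "ScoreTable", function(x) x@table)

#' @rdname ValidationReport-class
#' @export
setMethod("reportItemStats", "ValidationReport", function(x) x@itemStats)

#' @rdname ValidationReport-class
#' @export
setMethod("reportItemTables", "ValidationReport", function(x) x@itemTables)

#' @rdname ValidationReport-class
#' @export
setMethod("reportScaleStats", "ValidationReport", function(x) x@scaleStats)

#' @rdname ValidationReport-class
#' @export
setMethod("reportRecords", "ValidationReport", function(x) x@records)

setMethod("show", "ItemParameters", function(object) {
  cat("ItemParameters '", object@itemId, "' (", length(object@labels),
      " categories)\n", sep = "")
  if (nzchar(object@stem)) cat("  stem: ", object@stem, "\n", sep = "")
  cat("  labels: ", paste(object@labels, collapse = " | "), "\n", sep = "")
  cat("  slope: ", format(object@slope, digits = 4),
      "  thresholds: ", paste(format(object@thresholds, digits = 4),
                              collapse = ", "), "\n", sep = "")
})

setMethod("show", "ItemBank", function(object) {
  cat("ItemBank '", object@bankId, "': ", length(object@items),
      " items; T = ", object@center, " + ", object@scale, " * theta\n",
      sep = "")
  cat("  items: ", paste(itemIds(object), collapse = ", "), "\n", sep = "")
})

setMethod("show", "TScoreMap", function(object) {
  cat("TScoreMap for bank '", object@bankId, "' on [", object@tMin, ", ",
      object@tMax, ")\n", sep = "")
  cat("  ", nrow(object@bands), " bands across ",
      length(unique(object@bands$item_id)), " items", sep = "")
  if (nrow(object@omitted))
    cat("; ", nrow(object@omitted), " never-modal categories omitted",
        sep = "")
  cat("\n")
})

setMethod("show", "QuadratureGrid", function(object) {
  cat("QuadratureGrid: ", length(object@nodes), " nodes on [",
      format(min(object@nodes)), ", ", format(max(object@nodes)), "]\n",
      sep = "")
})

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable for bank '", object@bankId, "' (",
      nrow(object@table), " summed scores)\n", sep = "")
  print(utils::head(object@table, 4))
  if (nrow(object@table) > 4) cat("  ...\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport for bank '", object@bankId, "' (method: ",
      object@method, ")\n", sep = "")
  print(object@itemStats, row.names = FALSE)
  ss <- object@scaleStats
  cat(sprintf("Scale perfect-match: %.1f%% (%d of %d complete respondents)\n",
              ss$perfect_match_pct, ss$n_perfect, ss$n_complete))
  cat(sprintf("T-score mean %.1f, SD %.1f\n", ss$t_mean, ss$t_sd))
})
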