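# Readers and writers for the package's interchange formats: item banks
# (JSON, or a flat CSV dialect), response matrices (CSV), maps (JSON), and
# probability snapshots (CSV). All files are UTF-8; JSON output keeps full
# double precision and is byte-stable across runs.

#' Read an item bank
#'
#' JSON banks follow the schema
#' \code{{"bank_id", "metric": {"center", "scale"}, "items": [{"item_id",
#' "stem", "labels", "slope", "thresholds", "direction_note"}]}}.
#' A flat CSV dialect is also accepted (extension .csv): one row per item
#' with columns item_id, slope, threshold columns b1..b4 (as many as
#' needed), label columns label1..labelK, and optional stem and
#' direction_note; bank metadata comes from the arguments.
#'
#' @param path file to read.
#' @param bankId,center,scale bank metadata used for the CSV dialect
#'   (ignored for JSON, which carries its own).
#' @return An \linkS4class{ItemBank}.
#' @export
readBank <- function(path, bankId = "bank", center = 50, scale = 10) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    return(readBankCSV(path, bankId, center, scale))
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("bank_id", "items"))
    if (is.null(j[[f]])) stop("bank JSON missing field '", f, "'")
  items <- lapply(seq_along(j$items), function(i) {
    it <- j$items[[i]]
    for (f in c("item_id", "labels", "slope", "thresholds"))
      if (is.null(it[[f]]))
        stop("bank JSON: item ", i, " missing field '", f, "'")
    ItemParameters(
      itemId = it$item_id, labels = unlist(it$labels),
      slope = it$slope, thresholds = unlist(it$thresholds),
      stem = if (is.null(it$stem)) "" else it$stem,
      scalingConstant = if (is.null(it$scaling_constant)) 1
                        else it$scaling_constant,
      directionNote = if (is.null(it$direction_note)) ""
                      else it$direction_note)
  })
  m <- j$metric
  ItemBank(j$bank_id, items,
           center = if (is.null(m$center)) 50 else m$center,
           scale = if (is.null(m$scale)) 10 else m$scale)
}

readBankCSV <- function(path, bankId, center, scale) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("item_id", "slope") %in% names(d)))
    stop("bank CSV must have columns item_id and slope")
  bcols <- grep("^b[0-9]+$", names(d), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  lcols <- grep("^label[0-9]+$", names(d), value = TRUE)
  lcols <- lcols[order(as.integer(sub("^label", "", lcols)))]
  if (length(bcols) < 1L) stop("bank CSV needs threshold columns b1, b2, ...")
  items <- lapply(seq_len(nrow(d)), function(i) {
    b <- unlist(d[i, bcols]); b <- b[!is.na(b)]
    labs <- if (length(lcols)) unname(unlist(d[i, lcols]))[seq_len(length(b) + 1L)]
            else paste0("cat", seq_len(length(b) + 1L))
    ItemParameters(
      itemId = d$item_id[i], labels = labs, slope = d$slope[i],
      thresholds = unname(b),
      stem = if ("stem" %in% names(d)) d$stem[i] else "",
      directionNote = if ("direction_note" %in% names(d))
        d$direction_note[i] else "")
  })
  ItemBank(bankId, items, center = center, scale = scale)
}

#' Write an item bank as JSON
#'
#' @param bank an \linkS4class{ItemBank}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeBank <- function(bank, path) {
  stopifnot(is(bank, "ItemBank"))
  obj <- list(
    bank_id = bank@bankId,
    metric = list(center = bank@center, scale = bank@scale),
    items = lapply(bankItems(bank), function(it) list(
      item_id = it@itemId, stem = it@stem, labels = it@labels,
      slope = it@slope, thresholds = it@thresholds,
      scaling_constant = it@scalingConstant,
      direction_note = it@directionNote)))
  names(obj$items) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a response matrix CSV
#'
#' First column respondent_id, remaining columns item responses (category
#' codes 1..K; empty cells are missing). If a bank is supplied, columns and
#' codes are validated against it, with row-level error messages.
#'
#' @param path CSV file.
#' @param bank optional \linkS4class{ItemBank} to validate against.
#' @return data.frame of responses.
#' @export
readResponses <- function(path, bank = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 2L)
    stop("response CSV must have respondent_id plus item columns")
  names(d)[1L] <- "respondent_id"
  for (j in 2:ncol(d)) {
    v <- d[[j]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    vi <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & is.na(vi))
    if (length(bad))
      stop("response CSV column '", names(d)[j], "': non-integer value ",
           "in row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    d[[j]] <- vi
  }
  if (!is.null(bank)) asResponseMatrix(d, bank)  # validates, errors early
  d
}

#' Write a response matrix CSV
#'
#' @param responses data.frame (respondent_id + item columns).
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeResponses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a T-score map as JSON
#'
#' The JSON carries exact (full double precision) band endpoints together
#' with the map range, scan resolution, and any never-modal omitted
#' categories, so write-read round trips are value-identical.
#'
#' @param path file path.
#' @return \code{readMap}: a \linkS4class{TScoreMap}.
#' @export
readMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("bank_id", "t_min", "t_max", "bands"))
    if (is.null(j[[f]])) stop("map JSON missing field '", f, "'")
  bands <- as.data.frame(j$bands)
  bands$category <- as.integer(bands$category)
  omitted <- if (!is.null(j$omitted) && length(j$omitted)) {
    o <- as.data.frame(j$omitted); o$category <- as.integer(o$category); o
  } else data.frame(item_id = character(0), category = integer(0),
                    label = character(0), stringsAsFactors = FALSE)
  new("TScoreMap", bankId = j$bank_id, tMin = j$t_min, tMax = j$t_max,
      bands = bands, omitted = omitted,
      resolution = if (is.null(j$resolution)) NA_real_ else j$resolution)
}

#' @rdname readMap
#' @param map a \linkS4class{TScoreMap}.
#' @export
writeMap <- function(map, path) {
  stopifnot(is(map, "TScoreMap"))
  obj <- list(bank_id = map@bankId, t_min = map@tMin, t_max = map@tMax,
              resolution = map@resolution, bands = map@bands,
              omitted = map@omitted)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a probability-snapshot CSV
#'
#' Columns t, p1..pK: one row per T-score at which the full category
#' probability vector of an item is known (e.g. quoted in a publication).
#'
#' @param path CSV file.
#' @return Validated snapshot data.frame (see
#'   \code{\link{validateSnapshots}}).
#' @export
readSnapshots <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validateSnapshots(utils::read.csv(path, stringsAsFactors = FALSE))
}
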