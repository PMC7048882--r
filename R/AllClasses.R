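#' @import methods
NULL

#' GRM-calibrated item parameters
#'
#' Holds one item calibrated under Samejima's graded response model (GRM):
#' a positive discrimination (slope) on the logistic metric and K-1 strictly
#' increasing category thresholds on the latent theta metric, together with
#' the ordered response-category labels. Category codes run 1..K, ordered so
#' that a higher index corresponds to more of the measured domain; items whose
#' display order is reversed carry that mapping in \code{directionNote} and
#' are never re-ordered by the engine.
#'
#' @slot itemId character scalar, unique identifier within a bank.
#' @slot stem character scalar, the item wording.
#' @slot labels character vector of K ordered category labels (K >= 2).
#' @slot slope positive numeric, discrimination per theta unit (pure logistic
#'   metric; no 1.7 constant baked in).
#' @slot thresholds numeric vector of K-1 strictly increasing thresholds on
#'   the theta metric.
#' @slot scalingConstant numeric, multiplicative scaling constant applied to
#'   the slope inside the logistic (default 1; set 1.7 for banks calibrated
#'   on the normal-ogive-approximation metric).
#' @slot directionNote character scalar, free-text documentation of the
#'   presentation order of the response options.
#'
#' @export
setClass("ItemParameters",
  representation(
    itemId = "character",
    stem = "character",
    labels = "character",
    slope = "numeric",
    thresholds = "numeric",
    scalingConstant = "numeric",
    directionNote = "character"
  ),
  prototype(
    stem = "",
    scalingConstant = 1,
    directionNote = ""
  )
)

setValidity("ItemParameters", function(object) {
  msg <- character(0)
  if (length(object@itemId) != 1L || !nzchar(object@itemId))
    msg <- c(msg, "itemId must be a non-empty character scalar")
  K <- length(object@labels)
  if (K < 2L)
    msg <- c(msg, "at least 2 response categories are required")
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope <= 0)
    msg <- c(msg, "slope must be a single positive finite number")
  if (any(!is.finite(object@thresholds)))
    msg <- c(msg, "thresholds must be finite")
  else if (length(object@thresholds) >= 2L &&
           any(diff(object@thresholds) <= 0))
    msg <- c(msg, "thresholds must be strictly increasing")
  if (length(object@thresholds) != K - 1L)
    msg <- c(msg, sprintf(
      "expected %d thresholds for %d labels, got %d",
      K - 1L, K, length(object@thresholds)))
  if (length(object@scalingConstant) != 1L ||
      !is.finite(object@scalingConstant) || object@scalingConstant <= 0)
    msg <- c(msg, "scalingConstant must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an ItemParameters object
#'
#' @param itemId unique item identifier.
#' @param labels ordered character vector of K category labels.
#' @param slope positive discrimination per theta unit (logistic metric).
#' @param thresholds K-1 strictly increasing thresholds on the theta metric.
#' @param stem item wording (optional).
#' @param scalingConstant logistic scaling constant, default 1.
#' @param directionNote free-text note on response presentation order.
#' @return A validated \linkS4class{ItemParameters} object.
#' @examples
#' it <- ItemParameters("anx1", c("never", "rarely", "sometimes"),
#'                      slope = 2, thresholds = c(-1, 1))
#' categoryProbabilities(it, 0)
#' @export
ItemParameters <- function(itemId, labels, slope, thresholds, stem = "",
                           scalingConstant = 1, directionNote = "") {
  new("ItemParameters", itemId = as.character(itemId),
      stem = as.character(stem), labels = as.character(labels),
      slope = as.numeric(slope), thresholds = as.numeric(thresholds),
      scalingConstant = as.numeric(scalingConstant),
      directionNote = as.character(directionNote))
}

#' Item bank on a common latent metric
#'
#' An ordered collection of \linkS4class{ItemParameters} sharing one latent
#' trait, plus the affine map from theta to the reporting metric:
#' T = center + scale * theta. PROMIS-style banks use center 50, scale 10.
#'
#' @slot bankId character scalar.
#' @slot items list of \linkS4class{ItemParameters} with unique ids.
#' @slot center numeric, T-metric center (default 50).
#' @slot scale positive numeric, T-metric scale (default 10).
#' @export
setClass("ItemBank",
  representation(
    bankId = "character",
    items = "list",
    center = "numeric",
    scale = "numeric"
  ),
  prototype(center = 50, scale = 10)
)

setValidity("ItemBank", function(object) {
  msg <- character(0)
  if (length(object@bankId) != 1L || !nzchar(object@bankId))
    msg <- c(msg, "bankId must be a non-empty character scalar")
  if (length(object@items) < 1L)
    msg <- c(msg, "bank must contain at least one item")
  if (!all(vapply(object@items, is, logical(1), "ItemParameters")))
    msg <- c(msg, "all items must be ItemParameters objects")
  else {
    ids <- vapply(object@items, function(x) x@itemId, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicated item ids: %s",
                            paste(unique(ids[duplicated(ids)]),
                                  collapse = ", ")))
  }
  if (length(object@scale) != 1L || !is.finite(object@scale) ||
      object@scale <= 0)
    msg <- c(msg, "metric scale must be a single positive number")
  if (length(object@center) != 1L || !is.finite(object@center))
    msg <- c(msg, "metric center must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct an ItemBank
#'
#' @param bankId bank identifier.
#' @param items list of \linkS4class{ItemParameters}.
#' @param center,scale affine map T = center + scale * theta (defaults 50, 10).
#' @return A validated \linkS4class{ItemBank}.
#' @export
ItemBank <- function(bankId, items, center = 50, scale = 10) {
  new("ItemBank", bankId = as.character(bankId), items = items,
      center = as.numeric(center), scale = as.numeric(scale))
}

#' T-score map: modal-response bands over the score continuum
#'
#' For each item, the contiguous half-open T intervals [t_low, t_high) in
#' which each response category is the most probable (modal) response.
#' Bands tile [tMin, tMax) per item; categories that are never modal are
#' omitted and recorded separately.
#'
#' @slot bankId character scalar.
#' @slot tMin,tMax numeric range of the map on the T metric.
#' @slot bands data.frame with columns item_id, category, label, t_low,
#'   t_high; per item bands are ordered by (strictly increasing) category
#'   and exactly tile [tMin, tMax).
#' @slot omitted data.frame (item_id, category, label) of never-modal
#'   categories.
#' @slot resolution numeric, grid step (T units) of the modal scan whose
#'   change points were refined by bisection.
#' @export
setClass("TScoreMap",
  representation(
    bankId = "character",
    tMin = "numeric",
    tMax = "numeric",
    bands = "data.frame",
    omitted = "data.frame",
    resolution = "numeric"
  )
)

setValidity("TScoreMap", function(object) {
  msg <- character(0)
  b <- object@bands
  need <- c("item_id", "category", "label", "t_low", "t_high")
  if (!all(need %in% names(b)))
    msg <- c(msg, sprintf("bands must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (any(b$t_low >= b$t_high))
      msg <- c(msg, "each band must satisfy t_low < t_high")
    for (id in unique(b$item_id)) {
      bi <- b[b$item_id == id, , drop = FALSE]
      if (anyDuplicated(bi$category))
        msg <- c(msg, sprintf("item %s: category appears in >1 band", id))
      if (is.unsorted(bi$category, strictly = TRUE))
        msg <- c(msg, sprintf("item %s: band categories not increasing", id))
      if (abs(sum(bi$t_high - bi$t_low) - (object@tMax - object@tMin)) > 1e-6)
        msg <- c(msg, sprintf("item %s: bands do not tile the range", id))
    }
  }
  if (object@tMin >= object@tMax)
    msg <- c(msg, "tMin must be < tMax")
  if (length(msg)) msg else TRUE
})

#' Quadrature grid over the latent trait
#'
#' Equally spaced nodes with normalized normal-prior weights, used for EAP
#' scoring and population-expectation integrals.
#'
#' @slot nodes numeric vector of theta values.
#' @slot weights non-negative weights summing to 1.
#' @export
setClass("QuadratureGrid",
  representation(nodes = "numeric", weights = "numeric")
)

setValidity("QuadratureGrid", function(object) {
  msg <- character(0)
  if (length(object@nodes) != length(object@weights))
    msg <- c(msg, "nodes and weights must have equal length")
  if (any(object@weights < 0))
    msg <- c(msg, "weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-12)
    msg <- c(msg, "weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Summed-score-to-T conversion table
#'
#' One row per achievable summed score (categories coded 1..K sum from
#' n_items to sum of K_i), giving the EAP theta, its posterior SD, and the
#' corresponding T-score.
#'
#' @slot bankId character scalar.
#' @slot table data.frame with columns summed_score, theta_eap, theta_sd,
#'   t, t_sd; theta_eap strictly increasing in summed_score.
#' @export
setClass("ScoreTable",
  representation(bankId = "character", table = "data.frame")
)

setValidity("ScoreTable", function(object) {
  msg <- character(0)
  tb <- object@table
  need <- c("summed_score", "theta_eap", "theta_sd", "t", "t_sd")
  if (!all(need %in% names(tb)))
    msg <- c(msg, sprintf("table must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (is.unsorted(tb$summed_score, strictly = TRUE))
      msg <- c(msg, "summed_score must be strictly increasing")
    if (is.unsorted(tb$theta_eap, strictly = TRUE))
      msg <- c(msg, "theta_eap must be strictly increasing in summed score")
  }
  if (length(msg)) msg else TRUE
})

#' Predicted-versus-observed validation report
#'
#' Per-item difference-score distributions (observed minus predicted
#' category), exact and adjacent match percentages, Spearman correlations,
#' and the scale-level perfect-match rate.
#'
#' @slot bankId character scalar.
#' @slot method scoring method used ("summed" or "pattern").
#' @slot records data.frame of per-respondent, per-item predictions:
#'   respondent_id, t, item_id, predicted, observed, difference.
#' @slot itemTables named list (by item id) of difference-score tables
#'   (difference, n, percent).
#' @slot itemStats data.frame: item_id, n, exact_pct, minus1_pct, plus1_pct,
#'   spearman_r.
#' @slot scaleStats list: perfect_match_pct, n_complete, n_total, t_mean,
#'   t_sd.
#' @export
setClass("ValidationReport",
  representation(
    bankId = "character",
    method = "character",
    records = "data.frame",
    itemTables = "list",
    itemStats = "data.frame",
    scaleStats = "list"
  )
)
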