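#' Convert between the T metric and the latent theta metric
#'
#' The reporting metric is an affine transform of the latent trait:
#' T = center + scale * theta. PROMIS T-scores use center 50 and scale 10,
#' so T = 50 is the reference-population mean and each 10 T units is one
#' reference SD.
#'
#' @param t,theta numeric vectors of scores to convert.
#' @param center metric center (default 50).
#' @param scale metric scale, must be positive (default 10).
#' @return Numeric vector of converted scores.
#' @examples
#' thetaFromT(60)          # 1
#' tFromTheta(-2.5)        # 25
#' @export
thetaFromT <- function(t, center = 50, scale = 10) {
  stopifnot(is.numeric(t), length(scale) == 1L, is.finite(scale), scale > 0,
            length(center) == 1L, is.finite(center))
  if (any(!is.finite(t))) stop("non-finite T-score")
  (t - center) / scale
}

#' @rdname thetaFromT
#' @export
tFromTheta <- function(theta, center = 50, scale = 10) {
  stopifnot(is.numeric(theta), length(scale) == 1L, is.finite(scale),
            scale > 0, length(center) == 1L, is.finite(center))
  if (any(!is.finite(theta))) stop("non-finite theta")
  center + scale * theta
}

#' Boundary (cumulative) response probabilities
#'
#' Under the graded response model the probability of responding in category
#' k+1 or higher is a two-parameter logistic in theta:
#' P*_k(theta) = 1 / (1 + exp(-D a (theta - b_k))), k = 1..K-1, with common
#' slope a and increasing thresholds b_k (D is the item's scaling constant,
#' 1 by default). At any theta the K-1 boundary probabilities are strictly
#' decreasing in k.
#'
#' @param item an \linkS4class{ItemParameters} object.
#' @param theta numeric vector of latent-trait values.
#' @return For scalar theta, a numeric vector of K-1 boundary probabilities;
#'   for vector theta, a length(theta) x (K-1) matrix.
#' @examples
#' it <- ItemParameters("x", letters[1:3], slope = 2, thresholds = c(-1, 1))
#' boundaryProbabilities(it, 0)   # c(0.8808, 0.1192)
#' @export
boundaryProbabilities <- function(item, theta) {
  stopifnot(is(item, "ItemParameters"), is.numeric(theta))
  d <- item@scalingConstant * item@slope
  m <- stats::plogis(outer(theta, item@thresholds,
                           function(th, b) d * (th - b)))
  if (length(theta) == 1L) drop(m) else m
}

#' Category response probabilities (item characteristic curves)
#'
#' Probability of each response category 1..K at a given theta, as adjacent
#' differences of the boundary curves: P_k = P*_{k-1} - P*_k with P*_0 = 1
#' and P*_K = 0. These are the curves plotted in an ICC figure; at any score
#' the category whose curve is highest is the most probable response.
#'
#' @inheritParams boundaryProbabilities
#' @return For scalar theta, a numeric vector of K probabilities summing to
#'   1; for vector theta, a length(theta) x K matrix with unit row sums.
#' @examples
#' it <- ItemParameters("x", letters[1:3], slope = 2, thresholds = c(-1, 1))
#' categoryProbabilities(it, 0)   # c(0.1192, 0.7616, 0.1192)
#' @export
categoryProbabilities <- function(item, theta) {
  stopifnot(is(item, "ItemParameters"), is.numeric(theta))
  d <- item@scalingConstant * item@slope
  n <- length(theta)
  K <- length(item@labels)
  ps <- cbind(1, stats::plogis(outer(theta, item@thresholds,
                                     function(th, b) d * (th - b))), 0)
  out <- ps[, 1:K, drop = FALSE] - ps[, 2:(K + 1), drop = FALSE]
  colnames(out) <- item@labels
  if (n == 1L) drop(out) else out
}

#' Most probable (modal) response category
#'
#' The category whose characteristic curve is highest at the given theta.
#' Exact ties are broken toward the lower index, i.e. the less severe
#' response; under the continuous model ties occur only on a measure-zero
#' set of scores.
#'
#' @inheritParams boundaryProbabilities
#' @return Integer vector (same length as theta) of category indices 1..K.
#' @examples
#' it <- ItemParameters("x", c("no", "yes"), slope = 1, thresholds = 0)
#' modalCategory(it, c(-1, 0, 1))   # 1 1 2 (tie at 0 broken low)
#' @export
modalCategory <- function(item, theta) {
  p <- categoryProbabilities(item, theta)
  if (is.matrix(p)) {
    as.integer(max.col(p, ties.method = "first"))
  } else {
    as.integer(which.max(p))  # first max = lowest index on ties
  }
}
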