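# Inverse-fitting of GRM item parameters from printed probability snapshots,
# e.g. the five category probabilities quoted for an item at two T-scores.

#' Validate a snapshot table
#'
#' A snapshot table records the full category probability vector of one item
#' at one or more T-scores: a data.frame with a column `t` and probability
#' columns `p1..pK`. Probabilities must lie in [0,1] and each row must sum
#' to 1 within 1e-6; rows are renormalized to absorb rounding of printed
#' values.
#'
#' @param snapshots data.frame with columns t, p1..pK.
#' @param K expected number of categories (optional; inferred if NULL).
#' @return The validated snapshot table with renormalized rows.
#' @export
validateSnapshots <- function(snapshots, K = NULL) {
  snapshots <- as.data.frame(snapshots)
  if (!"t" %in% names(snapshots))
    stop("snapshot table must have a column 't'")
  pcols <- grep("^p[0-9]+$", names(snapshots), value = TRUE)
  pcols <- pcols[order(as.integer(sub("^p", "", pcols)))]
  if (is.null(K)) K <- length(pcols)
  if (length(pcols) != K || K < 2L)
    stop("snapshot table must have probability columns p1..pK (K >= 2); ",
         "found: ", paste(pcols, collapse = ", "))
  P <- as.matrix(snapshots[, pcols, drop = FALSE])
  if (any(!is.finite(P)) || any(P < 0) || any(P > 1))
    stop("snapshot probabilities must be finite and in [0, 1]")
  rs <- rowSums(P)
  # printed probabilities are typically rounded to 3 decimals; allow the
  # worst-case rounding slack of K/2 units in the last printed place
  bad <- which(abs(rs - 1) > 0.5 * K * 10^(-printedDecimals(P)) + 1e-6)
  if (length(bad))
    stop("snapshot row(s) ", paste(bad, collapse = ", "),
         " do not sum to 1 (sums: ",
         paste(format(rs[bad], digits = 6), collapse = ", "), ")")
  snapshots[, pcols] <- P / rs
  snapshots[, c("t", pcols)]
}

# smallest number of decimals that reproduces every probability exactly,
# capped at 6 (used only to size the rounding slack for printed inputs)
printedDecimals <- function(P) {
  for (d in 1:6) if (all(abs(P - round(P, d)) < 1e-12)) return(d)
  6L
}

#' Fit GRM item parameters to probability snapshots
#'
#' Recovers a slope and K-1 ordered thresholds from two or more full
#' category-probability vectors printed at known T-scores. The fit is a
#' deterministic least-squares inversion: each snapshot is converted to
#' cumulative (boundary) probabilities, clamped to [1e-6, 1-1e-6]; a
#' cumulative-logit linear regression provides the starting values; and
#' Levenberg-Marquardt least squares then minimizes the summed squared error
#' between model and observed category probabilities. Threshold ordering is
#' guaranteed by construction (the optimizer works on the first threshold
#' and log-increments), and no randomness is involved, so results are
#' machine-reproducible.
#'
#' @param snapshots data.frame with columns t, p1..pK (see
#'   \code{\link{validateSnapshots}}); at least two rows at distinct T.
#' @param K number of categories (optional, inferred from columns).
#' @param center,scale the T metric (defaults 50, 10).
#' @param itemId,stem,labels,directionNote metadata for the returned item;
#'   labels default to "cat1".."catK".
#' @return An \linkS4class{ItemParameters} object satisfying all class
#'   invariants.
#' @examples
#' snaps <- data.frame(t = c(45, 62),
#'   do.call(rbind, lapply(c(-0.5, 1.2), function(th)
#'     setNames(as.list(categoryProbabilities(
#'       ItemParameters("k", paste0("c", 1:5), 2.5,
#'                      c(-0.5, 0.2, 1.0, 1.8)), th)), paste0("p", 1:5)))))
#' fit <- fitItemFromSnapshots(snaps, itemId = "recovered")
#' itemSlope(fit)        # 2.5 recovered to numerical precision
#' @export
fitItemFromSnapshots <- function(snapshots, K = NULL, center = 50,
                                 scale = 10, itemId = "fitted_item",
                                 stem = "", labels = NULL,
                                 directionNote = "") {
  snapshots <- validateSnapshots(snapshots, K)
  K <- ncol(snapshots) - 1L
  if (nrow(snapshots) < 2L || length(unique(snapshots$t)) < 2L)
    stop("underdetermined fit: need at least 2 snapshots at distinct ",
         "T-scores (one slope + ", K - 1L, " thresholds)")
  theta <- thetaFromT(snapshots$t, center, scale)
  P <- as.matrix(snapshots[, -1, drop = FALSE])

  # cumulative P(X >= k+1), one column per boundary k = 1..K-1
  cum <- t(apply(P, 1L, function(p) rev(cumsum(rev(p)))[-1L]))
  if (K == 2L) cum <- matrix(cum, ncol = 1L)
  cum <- pmin(pmax(cum, 1e-6), 1 - 1e-6)
  nonMono <- apply(cum, 1L, function(x) any(diff(x) >= 0)) & (K > 2L)
  if (any(nonMono))
    stop("fit failure: snapshot row(s) ",
         paste(which(nonMono), collapse = ", "),
         " have non-decreasing cumulative probabilities after clamping; ",
         "category probabilities are not GRM-consistent")

  # cumulative-logit initialization: logit P*_k = a*theta - a*b_k is linear
  # in theta and a boundary intercept
  lg <- stats::qlogis(cum)
  dfr <- data.frame(y = as.vector(lg),
                    th = rep(theta, times = K - 1L),
                    k = factor(rep(seq_len(K - 1L), each = nrow(cum))))
  cf <- stats::coef(stats::lm(y ~ 0 + th + k, data = dfr))
  a0 <- max(cf[["th"]], 1e-3)
  b0 <- sort(-cf[-1L] / a0)
  b0 <- b0 + cumsum(c(0, pmax(0, 1e-4 - diff(b0))))  # enforce strict order

  # unconstrained reparameterization: log slope, first threshold,
  # log threshold increments
  par0 <- c(log(a0), b0[1L],
            if (K > 2L) log(pmax(diff(b0), 1e-4)))
  unpack <- function(par) {
    a <- exp(par[1L])
    b <- par[2L] + cumsum(c(0, if (K > 2L) exp(par[-(1:2)])))
    list(a = a, b = b)
  }
  resid <- function(par) {
    pb <- unpack(par)
    ps <- cbind(1, stats::plogis(outer(theta, pb$b,
                                       function(th, b) pb$a * (th - b))), 0)
    as.vector(ps[, 1:K, drop = FALSE] - ps[, 2:(K + 1), drop = FALSE] - P)
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid,
    control = minpack.lm::nls.lm.control(
      maxiter = 1000, ftol = 1e-15, ptol = 1e-15, gtol = 0))
  pb <- unpack(fit$par)
  if (is.null(labels)) labels <- paste0("cat", seq_len(K))
  ItemParameters(itemId = itemId, labels = labels, slope = pb$a,
                 thresholds = pb$b, stem = stem,
                 directionNote = directionNote)
}

#' Residuals of a fitted item against snapshots
#'
#' Model-minus-observed category probabilities for each snapshot row, used
#' as the fit-quality report of \code{\link{fitItemFromSnapshots}}.
#'
#' @param item an \linkS4class{ItemParameters} object.
#' @param snapshots snapshot data.frame (t, p1..pK).
#' @param center,scale the T metric.
#' @return List with elements \code{residuals} (rows = snapshots, columns =
#'   categories) and \code{maxAbsResidual}.
#' @export
snapshotResiduals <- function(item, snapshots, center = 50, scale = 10) {
  snapshots <- validateSnapshots(snapshots, nCategories(item))
  theta <- thetaFromT(snapshots$t, center, scale)
  model <- categoryProbabilities(item, theta)
  if (!is.matrix(model)) model <- matrix(model, nrow = 1L)
  res <- model - as.matrix(snapshots[, -1, drop = FALSE])
  rownames(res) <- paste0("t=", snapshots$t)
  list(residuals = res, maxAbsResidual = max(abs(res)))
}
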