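#' Pixel-wise confusion counts
#'
#' TP are cyst pixels correctly labeled cyst, FP non-cyst pixels labeled
#' cyst, FN cyst pixels labeled non-cyst; counts run over all pixels of
#' the (equal-shape) masks.
#'
#' @param pred,gt \linkS4class{CystMask} objects of equal shape.
#' @return named numeric vector with \code{TP}, \code{FP}, \code{FN}.
#' @seealso \code{\link{pixelMetrics}}
#' @export
pixelConfusion <- function(pred, gt) {
  stopifnot(is(pred, "CystMask"), is(gt, "CystMask"))
  if (!all(dim(pred) == dim(gt)))
    stop("pred and gt masks must have the same shape")
  p <- maskMatrix(pred); g <- maskMatrix(gt)
  c(TP = sum(p & g), FP = sum(p & !g), FN = sum(!p & g))
}

#' Pixel-wise IoU, precision and recall
#'
#' IoU = TP / (TP + FN + FP), Pr = TP / (TP + FP), Re = TP / (TP + FN).
#' A metric with zero denominator is undefined and returned as \code{NA}
#' (flagged, never coerced to 0 or 1). When all three are defined the
#' identity IoU = Pr * Re / (Pr + Re - Pr * Re) holds.
#'
#' @param confusion named vector with \code{TP}, \code{FP}, \code{FN}
#'   (from \code{\link{pixelConfusion}}, possibly summed over images).
#' @return named numeric vector \code{IoU}, \code{Pr}, \code{Re}.
#' @export
pixelMetrics <- function(confusion) {
  tp <- confusion[["TP"]]; fp <- confusion[["FP"]]; fn <- confusion[["FN"]]
  c(IoU = if (tp + fn + fp > 0) tp / (tp + fn + fp) else NA_real_,
    Pr = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    Re = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Match predicted and ground-truth cysts into DT/MS/WR
#'
#' Resolves the bipartite overlap graph between predicted and ground-truth
#' components into a one-to-one pairing. Candidate pairs are those
#' satisfying the detection rule (>= 1 shared pixel by default, or pairwise
#' pixel IoU > tau). Pairs are accepted greedily in descending pairwise
#' IoU, breaking ties by larger intersection area, then lower predicted
#' and ground-truth component id, so the matching is deterministic.
#'
#' Every matched ground-truth cyst is detected (DT); unmatched ground-truth
#' cysts are missed (MS); unmatched predictions are wrong (WR). A
#' ground-truth cyst overlapped by several predictions therefore yields one
#' DT and the surplus predictions count as WR; a prediction overlapping N
#' ground-truth cysts yields one DT and N - 1 MS.
#'
#' @param pred,gt \linkS4class{CystMask} or \linkS4class{CystComponents}
#'   objects over the same pixel grid.
#' @param config a \linkS4class{MatchConfig}.
#' @return a \linkS4class{CystMatch}.
#' @examples
#' gt <- CystMask(matrix(rep(c(TRUE, FALSE), c(4, 4)), 2, 4))
#' pr <- CystMask(cbind(c(TRUE, FALSE), c(FALSE, TRUE),
#'                      c(FALSE, FALSE), c(FALSE, FALSE)))
#' matchCounts(matchCysts(pr, gt))
#' @export
matchCysts <- function(pred, gt, config = matchConfig()) {
  if (is(pred, "CystMask")) pred <- labelComponents(pred)
  if (is(gt, "CystMask")) gt <- labelComponents(gt)
  stopifnot(is(pred, "CystComponents"), is(gt, "CystComponents"),
            is(config, "MatchConfig"))
  if (!all(dim(componentLabels(pred)) == dim(componentLabels(gt))))
    stop("pred and gt must share the pixel grid")
  nP <- nComponents(pred); nG <- nComponents(gt)
  pairs <- data.frame(pred = integer(0), gt = integer(0),
                      intersection = numeric(0), iou = numeric(0))
  if (nP > 0 && nG > 0) {
    ov <- cw_overlap_counts(componentLabels(pred), componentLabels(gt), nP, nG)
    idx <- which(ov$intersection > 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      inter <- ov$intersection[idx]
      un <- ov$predAreas[idx[, 1]] + ov$gtAreas[idx[, 2]] - inter
      iou <- inter / un
      cand <- data.frame(pred = idx[, 1], gt = idx[, 2],
                         intersection = inter, iou = iou)
      if (config@rule == "iou") cand <- cand[cand$iou > config@tau, ]
      cand <- cand[order(-cand$iou, -cand$intersection, cand$pred, cand$gt), ]
      pTaken <- logical(nP); gTaken <- logical(nG)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (!pTaken[cand$pred[i]] && !gTaken[cand$gt[i]]) {
          keep[i] <- TRUE
          pTaken[cand$pred[i]] <- TRUE
          gTaken[cand$gt[i]] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  matchedPred <- rep(NA_integer_, nP); matchedGt <- rep(NA_integer_, nG)
  if (nrow(pairs) > 0) {
    matchedPred[pairs$pred] <- pairs$gt
    matchedGt[pairs$gt] <- pairs$pred
  }
  dt <- nrow(pairs)
  new("CystMatch", dt = as.integer(dt), ms = as.integer(nG - dt),
      wr = as.integer(nP - dt), pairs = pairs,
      predAreas = as.integer(componentAreas(pred)),
      gtAreas = as.integer(componentAreas(gt)),
      matchedPred = matchedPred, matchedGt = matchedGt)
}

#' @rdname match-accessors
#' @export
setMethod("matchCounts", "CystMatch", function(x)
  c(DT = x@dt, MS = x@ms, WR = x@wr))

#' @rdname match-accessors
#' @export
setMethod("matchedPairs", "CystMatch", function(x) x@pairs)

#' Cyst-wise IoU, precision and recall
#'
#' IoU_cyst = DT / (DT + MS + WR), Pr_cyst = DT / (DT + WR),
#' Re_cyst = DT / (DT + MS), the object-level counterparts of the
#' pixel-wise metrics. A metric with zero denominator is undefined and
#' returned as \code{NA}.
#'
#' @param x a \linkS4class{CystMatch} or a named vector with \code{DT},
#'   \code{MS}, \code{WR} (e.g. counts summed over images).
#' @return named numeric vector \code{IoU_cyst}, \code{Pr_cyst},
#'   \code{Re_cyst}.
#' @export
cystMetrics <- function(x) {
  if (is(x, "CystMatch")) x <- matchCounts(x)
  dt <- x[["DT"]]; ms <- x[["MS"]]; wr <- x[["WR"]]
  c(IoU_cyst = if (dt + ms + wr > 0) dt / (dt + ms + wr) else NA_real_,
    Pr_cyst = if (dt + wr > 0) dt / (dt + wr) else NA_real_,
    Re_cyst = if (dt + ms > 0) dt / (dt + ms) else NA_real_)
}

#' Assign a cyst area to its size zone
#'
#' Zones are left-closed/right-open intervals on the boundary list: an area
#' below the first boundary falls in zone 1, an area equal to a boundary
#' falls in the zone starting there, and the last zone is unbounded above.
#'
#' @param area cyst area(s) in um^2, positive.
#' @param config a \linkS4class{ZoneConfig}.
#' @return integer zone index (1 to \code{length(boundaries) + 1}).
#' @examples
#' assignZone(c(30, 78, 1900), zoneConfig())  # zones 1, 3, 6
#' @export
assignZone <- function(area, config = zoneConfig()) {
  stopifnot(is(config, "ZoneConfig"))
  if (any(area <= 0)) stop("cyst areas must be positive")
  findInterval(area, config@boundaries) + 1L
}

#' Equal-cardinality zone boundaries from an area sample
#'
#' Boundaries are the k/n quantiles (k = 1..n-1) of the observed areas, so
#' the induced zones have equal cardinality up to rounding (+/-1 on
#' distinct areas). Degenerate samples (ties collapsing boundaries) raise
#' a warning.
#'
#' @param areas cyst areas in um^2, at least \code{nZones} of them.
#' @param nZones number of zones (default 6).
#' @return numeric vector of \code{nZones - 1} boundaries.
#' @export
computeZoneBoundaries <- function(areas, nZones = 6L) {
  if (length(areas) < nZones)
    stop("need at least as many areas as zones")
  if (nZones < 2L) return(numeric(0))
  b <- unname(stats::quantile(areas, probs = seq_len(nZones - 1L) / nZones,
                              type = 7))
  if (any(diff(b) <= 0))
    warning("degenerate boundaries: tied areas collapse some zones")
  b
}

#' Attribute DT/MS/WR counts to size zones
#'
#' The actual (ground-truth) size places DT and MS cysts; the predicted
#' size places WR cysts, whose true size does not exist. Per-zone counts
#' sum to the global DT/MS/WR.
#'
#' @param match a \linkS4class{CystMatch}.
#' @param config a \linkS4class{ZoneConfig} carrying the boundaries and the
#'   um-per-pixel scale used to convert component pixel areas to um^2.
#' @return data.frame with columns \code{zone}, \code{DT}, \code{MS},
#'   \code{WR}, one row per zone.
#' @export
zoneAttribution <- function(match, config = zoneConfig()) {
  stopifnot(is(match, "CystMatch"), is(config, "ZoneConfig"))
  nZones <- length(config@boundaries) + 1L
  scale <- config@micronsPerPixel^2
  out <- data.frame(zone = seq_len(nZones),
                    DT = 0L, MS = 0L, WR = 0L)
  gtZone <- if (length(match@gtAreas))
    assignZone(match@gtAreas * scale, config) else integer(0)
  predZone <- if (length(match@predAreas))
    assignZone(match@predAreas * scale, config) else integer(0)
  for (g in seq_along(gtZone)) {
    col <- if (is.na(match@matchedGt[g])) "MS" else "DT"
    out[gtZone[g], col] <- out[gtZone[g], col] + 1L
  }
  for (p in seq_along(predZone)) {
    if (is.na(match@matchedPred[p]))
      out[predZone[p], "WR"] <- out[predZone[p], "WR"] + 1L
  }
  out
}

#' Distribution of pairwise IoUs over detected pairs
#'
#' Pools the matched-pair pixel IoUs of one or more match results and
#' reports the empirical distribution: the sorted IoU values, their
#' cumulative fractions, and the fraction exceeding any query threshold.
#'
#' @param matches a \linkS4class{CystMatch} or a list of them.
#' @return an object of class \code{dtIouDistribution}: list with
#'   \code{iou} (sorted values) and \code{cumulative} (fraction of pairs
#'   with IoU <= each value).
#' @seealso \code{\link{fractionAbove}}
#' @export
dtIouDistribution <- function(matches) {
  if (is(matches, "CystMatch")) matches <- list(matches)
  ious <- unlist(lapply(matches, function(m) matchedPairs(m)$iou))
  ious <- sort(as.numeric(ious))
  structure(list(iou = ious,
                 cumulative = if (length(ious))
                   seq_along(ious) / length(ious) else numeric(0)),
            class = "dtIouDistribution")
}

#' @rdname dtIouDistribution
#' @param dist a \code{dtIouDistribution}.
#' @param threshold IoU threshold(s).
#' @return \code{fractionAbove}: the fraction of detected pairs with IoU
#'   strictly greater than each threshold.
#' @export
fractionAbove <- function(dist, threshold) {
  vapply(threshold, function(t) mean(dist$iou > t), numeric(1))
}

#' @export
print.dtIouDistribution <- function(x, ...) {
  cat(sprintf("dtIouDistribution: %d detected pairs", length(x$iou)))
  if (length(x$iou))
    cat(sprintf(", median IoU %.3f", stats::median(x$iou)))
  cat("\n")
  invisible(x)
}
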