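#' Build leave-one-tubule-out cross-validation folds
#'
#' Images from the same tubule are strongly correlated, so folds are built
#' at tubule level: one fold per tubule, whose images form the test set,
#' with the remaining tubules split into training and validation tubules
#' (a seeded random ~\code{valFraction} of them, at least one, become
#' validation). All images of a tubule stay together, and the three sets
#' are pairwise disjoint at tubule level within each fold. Construction is
#' reproducible under the seed and invariant to catalog row order.
#'
#' @param catalog a catalog data.frame (see \code{\link{readCatalog}}).
#' @param valFraction fraction of non-test tubules used for validation.
#' @param seed integer seed for the validation draw.
#' @return an object of class \code{lotoFolds}: a list of folds, each with
#'   \code{test} (one tubule key), \code{val} and \code{train} (tubule key
#'   vectors); tubule keys are \code{experiment/treatment/tubule}.
#' @export
buildLotoFolds <- function(catalog, valFraction = 0.2, seed = 1L) {
  validateCatalog(catalog)
  keys <- sort(unique(tubuleKeys(catalog)))
  n <- length(keys)
  if (n < 3L) stop("LOTO folds need at least 3 tubules, got ", n)
  if (valFraction <= 0 || valFraction >= 1)
    stop("valFraction must be in (0, 1)")
  set.seed(seed)
  folds <- lapply(keys, function(testKey) {
    rest <- setdiff(keys, testKey)
    nVal <- max(1L, ceiling(valFraction * length(rest)))
    val <- sort(sample(rest, nVal))
    list(test = testKey, val = val, train = sort(setdiff(rest, val)))
  })
  structure(folds, class = "lotoFolds")
}

#' @export
print.lotoFolds <- function(x, ...) {
  cat(sprintf("lotoFolds: %d folds (one test tubule each), %d/%d train/val tubules per fold\n",
              length(x), length(x[[1]]$train), length(x[[1]]$val)))
  invisible(x)
}

#' Subset a catalog to one side of a fold
#'
#' @param catalog a catalog data.frame.
#' @param fold one element of a \code{lotoFolds} object.
#' @param role \code{"test"}, \code{"val"} or \code{"train"}.
#' @return the catalog rows whose tubule key belongs to the requested side.
#' @export
foldImages <- function(catalog, fold, role = c("test", "val", "train")) {
  role <- match.arg(role)
  catalog[tubuleKeys(catalog) %in% fold[[role]], , drop = FALSE]
}

#' Aggregate per-image confusion records
#'
#' Within a group, raw confusion counts are summed and the six metrics
#' recomputed from the sums (micro-aggregation), which keeps tubule-level
#' metrics insensitive to how cysts are distributed across a tubule's
#' images. Across groups, each defined metric is summarized as mean +/-
#' the 95% normal-approximation half-width over groups
#' (macro-aggregation). Undefined (NA) group metrics are excluded from the
#' cross-group summary, never coerced.
#'
#' @param records data.frame with one row per image carrying the count
#'   columns \code{TP}, \code{FP}, \code{FN}, \code{DT}, \code{MS},
#'   \code{WR} and the grouping column.
#' @param groupBy name of the grouping column (e.g. \code{"tubule_key"},
#'   \code{"treatment_id"}).
#' @return list with \code{perGroup} (counts and metrics per group) and
#'   \code{summary} (mean, half-width and group count per metric).
#' @export
aggregateConfusions <- function(records, groupBy = "tubule_key") {
  counts <- c("TP", "FP", "FN", "DT", "MS", "WR")
  stopifnot(all(c(counts, groupBy) %in% names(records)))
  groups <- split(records, records[[groupBy]])
  if (length(groups) == 0L) stop("no groups to aggregate")
  perGroup <- do.call(rbind, lapply(names(groups), function(g) {
    sums <- colSums(groups[[g]][, counts, drop = FALSE])
    pm <- pixelMetrics(sums)
    cm <- cystMetrics(c(DT = sums[["DT"]], MS = sums[["MS"]],
                        WR = sums[["WR"]]))
    cbind(data.frame(group = g, nImages = nrow(groups[[g]])),
          as.data.frame(as.list(c(sums, pm, cm))))
  }))
  names(perGroup)[1] <- groupBy
  metrics <- c("IoU", "Pr", "Re", "IoU_cyst", "Pr_cyst", "Re_cyst")
  summary <- do.call(rbind, lapply(metrics, function(m) {
    v <- perGroup[[m]]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      return(data.frame(metric = m, mean = NA_real_,
                        halfWidth = NA_real_, nGroups = 0L))
    hw <- if (length(v) > 1L) 1.96 * stats::sd(v) / sqrt(length(v)) else 0
    data.frame(metric = m, mean = mean(v), halfWidth = hw,
               nGroups = length(v))
  }))
  list(perGroup = perGroup, summary = summary)
}

#' Per-treatment performance report
#'
#' Aggregates confusion records by treatment and reports, per metric, the
#' spread (maximum pairwise difference) across treatments -- the
#' treatment-invariance check: a robust pipeline shows a small spread.
#'
#' @param records per-image confusion records carrying
#'   \code{treatment_id}.
#' @return the \code{\link{aggregateConfusions}} result plus
#'   \code{spread}, a named vector of per-metric max pairwise differences.
#' @export
treatmentReport <- function(records) {
  agg <- aggregateConfusions(records, groupBy = "treatment_id")
  metrics <- c("IoU", "Pr", "Re", "IoU_cyst", "Pr_cyst", "Re_cyst")
  agg$spread <- vapply(metrics, function(m)
    metricSpread(agg$perGroup[[m]]), numeric(1))
  agg
}

#' Maximum pairwise difference of a metric vector
#'
#' @param x numeric metric values (NAs dropped).
#' @return \code{max(x) - min(x)}, or \code{NA} if fewer than two values.
#' @export
metricSpread <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  max(x) - min(x)
}

#' Evaluate predictions over a catalog
#'
#' Runs the evaluation phase end-to-end for every catalog image: obtain
#' the predicted mask (from a directory of mask PNGs named
#' \code{<image_id>.png}, or by running a segmentation backend on the
#' image and binarizing), postprocess it (hole filling, then the optional
#' morphological operation), rasterize the ground-truth annotation, and
#' compute pixel-wise and cyst-wise confusions with the overlap matching.
#'
#' @param catalog a catalog data.frame.
#' @param dataDir directory that catalog paths are relative to.
#' @param predictions either a directory of predicted mask PNGs or a
#'   \linkS4class{SegmentationBackend}.
#' @param threshold binarization threshold used when predictions come from
#'   a backend.
#' @param match a \linkS4class{MatchConfig}.
#' @param morph a \linkS4class{MorphConfig} for postprocessing.
#' @param fill apply flood-fill hole filling before morphology.
#' @param zones a \linkS4class{ZoneConfig}.
#' @param connectivity component connectivity for both masks.
#' @return list with \code{records} (per-image counts and metadata),
#'   \code{matches} (per-image \linkS4class{CystMatch}), \code{zoneTable}
#'   (summed per-zone DT/MS/WR with cyst-wise metrics), \code{iouDist}
#'   (the pooled detected-pair IoU distribution) and \code{overall}
#'   (micro-aggregated six metrics over all images).
#' @export
evaluateCatalog <- function(catalog, dataDir = ".", predictions,
                            threshold = 0.5, match = matchConfig(),
                            morph = morphConfig("none"), fill = TRUE,
                            zones = zoneConfig(), connectivity = 8L) {
  validateCatalog(catalog)
  useBackend <- is(predictions, "SegmentationBackend")
  if (!useBackend && !dir.exists(predictions))
    stop("predictions must be a SegmentationBackend or an existing directory")
  records <- NULL
  matches <- list()
  missing <- character(0)
  for (i in seq_len(nrow(catalog))) {
    id <- catalog$image_id[i]
    annPath <- file.path(dataDir, catalog$annotation_path[i])
    imgPath <- file.path(dataDir, catalog$image_path[i])
    if (!file.exists(annPath)) { missing <- c(missing, id); next }
    if (useBackend) {
      img <- readImageRGB(imgPath)
      prob <- predictProbabilities(predictions, img)
      pred <- binarizeProbabilities(prob, threshold, connectivity)
      hw <- dim(img)[1:2]
    } else {
      predPath <- file.path(predictions, paste0(id, ".png"))
      if (!file.exists(predPath)) { missing <- c(missing, id); next }
      pred <- readMask(predPath, connectivity)
      hw <- dim(pred)
    }
    pred <- postprocessMask(pred, morph, fill = fill)
    gt <- rasterizeAnnotations(readLabelme(annPath), width = hw[2],
                               height = hw[1], connectivity = connectivity)
    pc <- pixelConfusion(pred, gt)
    mt <- matchCysts(pred, gt, match)
    matches[[id]] <- mt
    records <- rbind(records, data.frame(
      image_id = id,
      experiment_id = catalog$experiment_id[i],
      treatment_id = catalog$treatment_id[i],
      tubule_key = tubuleKeys(catalog[i, , drop = FALSE]),
      TP = pc[["TP"]], FP = pc[["FP"]], FN = pc[["FN"]],
      DT = mt@dt, MS = mt@ms, WR = mt@wr,
      stringsAsFactors = FALSE))
  }
  if (length(missing))
    stop("catalog entries without annotation or prediction: ",
         paste(missing, collapse = ", "))
  zoneTable <- Reduce(function(a, b) {
    a[, c("DT", "MS", "WR")] <- a[, c("DT", "MS", "WR")] +
      b[, c("DT", "MS", "WR")]
    a
  }, lapply(matches, zoneAttribution, config = zones))
  zoneTable <- cbind(zoneTable, t(apply(zoneTable[, c("DT", "MS", "WR")], 1,
    function(r) cystMetrics(c(DT = r[[1]], MS = r[[2]], WR = r[[3]])))))
  sums <- colSums(records[, c("TP", "FP", "FN", "DT", "MS", "WR")])
  overall <- c(pixelMetrics(sums),
               cystMetrics(c(DT = sums[["DT"]], MS = sums[["MS"]],
                             WR = sums[["WR"]])))
  list(records = records, matches = matches, zoneTable = zoneTable,
       iouDist = dtIouDistribution(matches), overall = overall)
}
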