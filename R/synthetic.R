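#' Generate a synthetic tubule fluorescence scene
#'
#' Renders the visual model a human annotator relies on: a red tissue band
#' (the tubule) crossing the canvas, point-like blue nuclei scattered over
#' the tissue and densified in rings around cyst rims, cyst lumens that are
#' dark voids in both red and blue, and a green channel of pure noise.
#' Cysts are modeled as mildly rotated ellipses, stored as 48-gon polygons;
#' the ground-truth mask is exactly the rasterization of those polygons,
#' and cysts are pairwise disjoint by construction.
#'
#' Cyst areas are drawn from a log-normal distribution (median 78 um^2,
#' sdlog 0.9) truncated to 30--2000 um^2; per-image counts from a Poisson
#' with mean 4, capped at 12. Identical config (including seed) yields a
#' bit-identical scene. If a cyst cannot be placed disjointly after bounded
#' retries, an error of class \code{cystwisePlacementError} reports the
#' achieved count.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return a \linkS4class{SyntheticScene}.
#' @examples
#' sc <- generateScene(sceneConfig(width = 128, height = 128, nCysts = 3,
#'                                 micronsPerPixel = 1, seed = 7))
#' nComponents(labelComponents(sc@gtMask))
#' @export
generateScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  set.seed(config@seed)
  H <- config@height; W <- config@width
  mpp <- config@micronsPerPixel

  n <- if (is.na(config@nCysts)) min(stats::rpois(1L, 4), 12L) else config@nCysts

  # tubule band: horizontal with wobbling edges; bandFraction >= 0.5 makes
  # the tissue fill the frame (close-up of the tubule wall)
  rowIdx <- matrix(seq_len(H), H, W)
  midRow <- H / 2 + (H / 12) * sin(2 * pi * seq_len(W) / W +
                                   stats::runif(1, 0, 2 * pi))
  halfW <- H * config@bandFraction * (1 + 0.1 * cos(2 * pi * seq_len(W) / W))
  tissue <- abs(rowIdx - matrix(midRow, H, W, byrow = TRUE)) <
    matrix(halfW, H, W, byrow = TRUE)

  geometries <- list()
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  for (i in seq_len(n)) {
    areaUm <- .rlnormTrunc(config@areaMeanlog, config@areaSdlog,
                           config@areaRange)
    areaPx <- areaUm / mpp^2
    ratio <- stats::runif(1, 0.6, 1)
    a <- sqrt(areaPx / (pi * ratio))
    b <- a * ratio
    rot <- stats::runif(1, 0, pi)
    placed <- FALSE
    for (try in seq_len(200L)) {
      cx <- stats::runif(1, a + config@margin, W - a - config@margin)
      if (halfW[round(cx)] - a - config@margin <= 0) next
      cy <- midRow[round(cx)] +
        stats::runif(1, -1, 1) * (halfW[round(cx)] - a - config@margin)
      if (cy < a + config@margin || cy > H - a - config@margin) next
      if (nrow(centers) > 0) {
        d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (any(d < radii + a + config@margin)) next
      }
      placed <- TRUE
      break
    }
    if (!placed) {
      cond <- simpleError(sprintf(
        "could not place cyst %d of %d after bounded retries (achieved %d)",
        i, n, length(geometries)))
      class(cond) <- c("cystwisePlacementError", class(cond))
      stop(cond)
    }
    t <- seq(0, 2 * pi, length.out = 49L)[-49L]
    poly <- cbind(x = cx + a * cos(rot) * cos(t) - b * sin(rot) * sin(t),
                  y = cy + a * sin(rot) * cos(t) + b * cos(rot) * sin(t))
    centers <- rbind(centers, c(cx, cy))
    radii <- c(radii, a)
    geometries[[i]] <- list(polygon = poly, center = c(x = cx, y = cy),
                            axes = c(a = a, b = b), rotation = rot,
                            areaUm2 = areaUm)
  }

  ann <- AnnotationSet("scene", lapply(geometries, `[[`, "polygon"))
  gtMask <- if (length(geometries) > 0) rasterizeAnnotations(ann, W, H)
            else CystMask(matrix(FALSE, H, W))
  gt <- maskMatrix(gtMask)

  # red: tissue with mild texture, lumens nearly void
  red <- config@tissueIntensity * tissue *
    (1 + 0.08 * matrix(stats::rnorm(H * W), H, W))
  red[gt] <- red[gt] * 0.12

  # blue: nuclei dots over tissue plus rings hugging each cyst rim
  blue <- matrix(0, H, W)
  nNuc <- round(config@nucleiDensity * sum(tissue) / 1000)
  if (nNuc > 0) {
    idx <- sample(which(tissue & !gt), min(nNuc, sum(tissue & !gt)))
    blue <- .stampNuclei(blue, ((idx - 1L) %% H) + 1L, ((idx - 1L) %/% H) + 1L)
  }
  for (g in geometries) {
    per <- 2 * pi * mean(g$axes)
    nr <- max(6L, round(per / 4))
    t <- stats::runif(nr, 0, 2 * pi)
    grow <- 1 + (1.5 + abs(stats::rnorm(nr, 0, 0.7))) / mean(g$axes)
    xs <- g$center["x"] + grow * (g$axes["a"] * cos(g$rotation) * cos(t) -
                                  g$axes["b"] * sin(g$rotation) * sin(t))
    ys <- g$center["y"] + grow * (g$axes["a"] * sin(g$rotation) * cos(t) +
                                  g$axes["b"] * cos(g$rotation) * sin(t))
    keep <- xs >= 2 & xs <= W - 1 & ys >= 2 & ys <= H - 1
    blue <- .stampNuclei(blue, round(ys[keep]), round(xs[keep]))
  }
  blue[gt] <- blue[gt] * 0.05
  blue <- blue + 0.02 * tissue

  # green: pure noise
  green <- matrix(abs(stats::rnorm(H * W, 0, config@greenNoise)), H, W)

  img <- array(0, c(H, W, 3L))
  img[, , 1] <- pmin(pmax(red +
    0.02 * matrix(stats::rnorm(H * W), H, W), 0), 1)
  img[, , 2] <- pmin(green, 1)
  img[, , 3] <- pmin(pmax(blue, 0), 1)

  new("SyntheticScene", image = img, gtMask = gtMask,
      geometries = geometries, config = config)
}

# truncated log-normal draw by rejection (bounds are loose so this is cheap)
.rlnormTrunc <- function(meanlog, sdlog, range) {
  for (i in seq_len(1000L)) {
    x <- stats::rlnorm(1, meanlog, sdlog)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  stats::runif(1, range[1], range[2])
}

# stamp 3x3 soft nucleus dots at the given (row, col) positions
.stampNuclei <- function(mat, rows, cols) {
  H <- nrow(mat); W <- ncol(mat)
  for (dr in -1:1) for (dc in -1:1) {
    w <- if (dr == 0 && dc == 0) 0.9 else 0.45
    r <- rows + dr; c <- cols + dc
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    idx <- cbind(r[ok], c[ok])
    mat[idx] <- pmin(mat[idx] + w, 1)
  }
  mat
}

#' Perturb a ground-truth mask into a synthetic prediction
#'
#' Corrupts a ground-truth mask with known, logged operations so the
#' detected/missed/wrong outcome of downstream matching is determined in
#' advance: whole components are dropped, split in two by a narrow
#' background cut through the centroid, or boundary-jittered (random
#' erosion or dilation); small spurious blobs are added disjoint from all
#' ground-truth components. Rates draw randomly; \code{dropIds},
#' \code{splitIds} and \code{spuriousExact} in the config pin the outcome
#' exactly for known-answer fixtures.
#'
#' @param gt a \linkS4class{CystMask} (the ground truth).
#' @param config a \linkS4class{PerturbConfig}.
#' @param micronsPerPixel scale used to size spurious blobs from the
#'   smallest-cyst zone (wrong predictions are typically very small).
#' @return a list with \code{pred} (a \linkS4class{CystMask}) and
#'   \code{log}: \code{components} (data.frame of component, action) and
#'   \code{spurious} (data.frame of row, col, areaPx).
#' @export
perturbMask <- function(gt, config, micronsPerPixel = 0.5) {
  stopifnot(is(gt, "CystMask"), is(config, "PerturbConfig"))
  set.seed(config@seed)
  comps <- labelComponents(gt)
  lab <- componentLabels(comps)
  n <- nComponents(comps)
  H <- nrow(lab); W <- ncol(lab)

  drop <- if (length(config@dropIds)) seq_len(n) %in% config@dropIds
          else stats::runif(n) < config@dropRate
  splt <- if (length(config@splitIds)) seq_len(n) %in% config@splitIds
          else stats::runif(n) < config@splitRate
  splt <- splt & !drop

  pred <- matrix(FALSE, H, W)
  action <- character(n)
  for (i in seq_len(n)) {
    if (drop[i]) { action[i] <- "dropped"; next }
    pix <- lab == i
    if (splt[i]) {
      action[i] <- "split"
      idx <- which(pix, arr.ind = TRUE)
      cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
      theta <- stats::runif(1, 0, pi)
      # signed distance of each pixel center to the cut line
      d <- -(idx[, 2] - cx) * sin(theta) + (idx[, 1] - cy) * cos(theta)
      pix[idx[abs(d) <= config@splitWidth / 2, , drop = FALSE]] <- FALSE
    } else {
      action[i] <- "kept"
    }
    if (config@boundaryJitter > 0L) {
      op <- if (stats::runif(1) < 0.5) "opening" else "closing"
      # pure erosion or dilation of this component by the jitter radius
      k <- 2L * config@boundaryJitter + 1L
      pix <- if (op == "opening") .morphRaw(pix, "erode", k)
             else .morphRaw(pix, "dilate", k)
    }
    pred <- pred | pix
  }

  nSpur <- if (config@spuriousExact) as.integer(round(config@spuriousRate))
           else stats::rpois(1L, config@spuriousRate)
  forbidden <- .morphRaw(maskMatrix(gt) | pred, "dilate", 5L)
  spur <- data.frame(row = integer(0), col = integer(0), areaPx = integer(0))
  for (s in seq_len(nSpur)) {
    areaUm <- stats::runif(1, 8, 33)               # below the smallest zone
    r <- max(1.5, sqrt(areaUm / micronsPerPixel^2 / pi))
    done <- FALSE
    for (try in seq_len(100L)) {
      cy <- stats::runif(1, r + 2, H - r - 2)
      cx <- stats::runif(1, r + 2, W - r - 2)
      rr <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
      cc <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
      blob <- outer(rr - cy, cc - cx, function(a, b) a^2 + b^2) <= r^2
      if (!any(blob)) next
      if (any(forbidden[rr, cc] & blob)) next
      sub <- pred[rr, cc]; sub[blob] <- TRUE; pred[rr, cc] <- sub
      forbidden[rr, cc] <- forbidden[rr, cc] | blob
      spur <- rbind(spur, data.frame(row = round(cy), col = round(cx),
                                     areaPx = sum(blob)))
      done <- TRUE
      break
    }
    if (!done) warning("could not place spurious blob ", s, " disjointly")
  }

  list(pred = CystMask(pred, connectivity = connectivity(gt)),
       log = list(components = data.frame(component = seq_len(n),
                                          action = action,
                                          stringsAsFactors = FALSE),
                  spurious = spur))
}

#' Build a synthetic catalog without rendering images
#'
#' Creates a catalog data.frame mirroring the study layout -- experiments
#' holding treatments, up to two tubules per treatment, several z-stack
#' images per tubule -- for tests of fold construction and aggregation
#' that need structure but not pixels.
#'
#' @param nTubules total number of tubules.
#' @param imagesPerTubule images (z slices) per tubule.
#' @param nExperiments number of experiments to spread tubules over.
#' @param treatmentsPerExperiment treatments per experiment.
#' @return a catalog data.frame (paths are placeholders).
#' @export
syntheticCatalog <- function(nTubules = 32L, imagesPerTubule = 4L,
                             nExperiments = 4L,
                             treatmentsPerExperiment = 4L) {
  rows <- list()
  tub <- 0L
  while (tub < nTubules) {
    tub <- tub + 1L
    e <- ((tub - 1L) %/% (treatmentsPerExperiment * 2L)) %% nExperiments + 1L
    tr <- ((tub - 1L) %/% 2L) %% treatmentsPerExperiment + 1L
    tu <- (tub - 1L) %% 2L + 1L
    for (z in seq_len(imagesPerTubule)) {
      id <- sprintf("E%d_T%d_tub%d_z%02d", e, tr, tu, z)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, experiment_id = sprintf("E%d", e),
        treatment_id = sprintf("TREAT_%d", tr),
        tubule_id = sprintf("tub%d", tu), z_index = z,
        image_path = paste0("images/", id, ".png"),
        annotation_path = paste0("annotations/", id, ".json"),
        stringsAsFactors = FALSE)
    }
  }
  cat <- do.call(rbind, rows)
  # keep exactly nTubules tubules
  keys <- tubuleKeys(cat)
  keep <- keys %in% unique(keys)[seq_len(nTubules)]
  cat <- cat[keep, , drop = FALSE]
  rownames(cat) <- NULL
  cat
}

#' Write a synthetic dataset to disk
#'
#' Generates scenes tubule by tubule and writes, per image, the rendered
#' PNG, the ground-truth mask PNG and a Labelme-dialect JSON annotation,
#' plus one catalog CSV -- so synthetic data flows through exactly the same
#' readers as microscope data.
#'
#' @param dir output directory (created if missing).
#' @param nTubules,imagesPerTubule dataset shape.
#' @param config base \linkS4class{SceneConfig}; per-image seeds are
#'   derived from \code{seed}.
#' @param seed integer master seed.
#' @param force overwrite a non-empty directory.
#' @return the catalog data.frame, invisibly.
#' @export
generateDataset <- function(dir, nTubules = 4L, imagesPerTubule = 4L,
                            config = sceneConfig(), seed = 1L,
                            force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("output directory '", dir, "' is not empty (use force = TRUE)")
  for (d in c("", "images", "masks", "annotations"))
    dir.create(file.path(dir, d), showWarnings = FALSE, recursive = TRUE)
  cat <- syntheticCatalog(nTubules, imagesPerTubule)
  for (i in seq_len(nrow(cat))) {
    sc <- generateScene(.replaceSeed(config, (seed * 1000L + i) %%
                                       .Machine$integer.max))
    id <- cat$image_id[i]
    writeImageRGB(sc@image, file.path(dir, "images", paste0(id, ".png")))
    writeMask(sc@gtMask, file.path(dir, "masks", paste0(id, ".png")))
    ann <- AnnotationSet(id, lapply(sc@geometries, `[[`, "polygon"))
    writeLabelme(ann, file.path(dir, "annotations", paste0(id, ".json")),
                 imageHeight = config@height, imageWidth = config@width,
                 imagePath = paste0(id, ".png"))
  }
  cat$image_path <- file.path("images", paste0(cat$image_id, ".png"))
  cat$annotation_path <- file.path("annotations", paste0(cat$image_id, ".json"))
  writeCatalog(cat, file.path(dir, "catalog.csv"))
  invisible(cat)
}

.replaceSeed <- function(config, seed) {
  config@seed <- as.integer(seed)
  config
}
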