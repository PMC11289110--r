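#' Binarize a probability map
#'
#' A pixel is cyst iff its probability is strictly greater than the
#' threshold (default 0.5; ties fall to background).
#'
#' @param probabilities numeric matrix with values in [0, 1].
#' @param threshold binarization threshold, in (0, 1).
#' @param connectivity connectivity attached to the mask.
#' @return a \linkS4class{CystMask}.
#' @export
binarizeProbabilities <- function(probabilities, threshold = 0.5,
                                  connectivity = 8L) {
  if (threshold <= 0 || threshold >= 1)
    stop("binarization threshold must be in (0, 1)")
  if (min(probabilities) < 0 || max(probabilities) > 1)
    stop("probabilities must lie in [0, 1]")
  CystMask(probabilities > threshold, connectivity = connectivity)
}

#' Cosine annealing learning rate with warm restarts
#'
#' The learning rate decays along a half cosine from its initial value to
#' \code{etaMin} over a cycle, then restarts. The first cycle lasts
#' \code{t0} epochs and each subsequent cycle is \code{tMult} times longer,
#' so with t0 = 10 and tMult = 2 the rate restarts at the epoch-10 and
#' epoch-30 boundaries (epochs 11 and 31 start at the full rate).
#'
#' @param epoch 1-based epoch index (vectorized).
#' @param lr0 initial learning rate.
#' @param t0 first cycle length in epochs.
#' @param tMult cycle length multiplier.
#' @param etaMin floor learning rate.
#' @return the learning rate(s) for the given epoch(s).
#' @export
cosineAnnealingSchedule <- function(epoch, lr0 = 1e-4, t0 = 10L, tMult = 2L,
                                    etaMin = 0) {
  vapply(epoch, function(e) {
    tcur <- e - 1L
    ti <- t0
    while (tcur >= ti) {
      tcur <- tcur - ti
      ti <- ti * tMult
    }
    etaMin + 0.5 * (lr0 - etaMin) * (1 + cos(pi * tcur / ti))
  }, numeric(1))
}

#' @describeIn predictProbabilities red-darkness baseline: high probability
#'   for dark pixels enclosed by bright (tissue) red signal, a logistic
#'   ramp on the red intensity elsewhere inside the tissue.
#' @export
setMethod("predictProbabilities", "ThresholdBackend", function(backend, image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  red <- image[, , 1]
  tissue <- CystMask(red > backend@cutoff)
  enclosed <- maskMatrix(fillHoles(tissue)) & !maskMatrix(tissue)
  p <- stats::plogis(backend@slope * (backend@cutoff - red)) * enclosed
  pmin(pmax(p, 0), 1)
})

#' @describeIn predictProbabilities the reference network: mutes the green
#'   channel, normalizes with the stored statistics, pads to a multiple of
#'   4, and runs the encoder-decoder. Deterministic for fixed weights.
#' @export
setMethod("predictProbabilities", "ReferenceNet", function(backend, image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  x <- normalizeChannels(removeGreen(image),
                         backend@channelMeans, backend@channelStds)
  d <- dim(x)
  H4 <- 4L * ceiling(d[1] / 4); W4 <- 4L * ceiling(d[2] / 4)
  if (H4 != d[1] || W4 != d[2]) {
    xp <- array(0, c(H4, W4, 3L))
    xp[seq_len(d[1]), seq_len(d[2]), ] <- x
    x <- xp
  }
  z <- .netForward(backend@weights, x)$logits
  stats::plogis(z[seq_len(d[1]), seq_len(d[2]), drop = FALSE])
})

#' Train the compact reference network
#'
#' Trains the miniature encoder-decoder with the standard recipe: binary
#' cross-entropy between predicted probabilities and the mask, Adam at the
#' configured learning rate under cosine annealing with warm restarts,
#' batches of \code{batchSize} images (gradients averaged over the batch),
#' early stopping when the validation pixel-wise IoU -- accumulated over
#' the whole validation set at the configured binarization threshold --
#' fails to improve for \code{patience} epochs, and at most
#' \code{maxEpochs} epochs. The returned weights are those of the best
#' validation epoch. Training is reproducible under the config seed on a
#' fixed-thread CPU run.
#'
#' @param trainSet,valSet lists of samples, each a list with \code{image}
#'   (height x width x 3 array in [0, 1], height/width multiples of 4) and
#'   \code{mask} (a \linkS4class{CystMask} or logical matrix). Train and
#'   validation sets must come from disjoint tubules.
#' @param config a \linkS4class{TrainConfig}.
#' @param channels the three encoder widths.
#' @param augment optional \linkS4class{AugmentConfig} applied per sample
#'   per epoch (its normalization flag is ignored: the network always
#'   normalizes internally).
#' @param verbose log one line per epoch to stderr.
#' @return list with \code{backend} (a \linkS4class{ReferenceNet} holding
#'   the best-epoch weights) and \code{history} (data.frame of epoch,
#'   learning rate, training loss, validation IoU).
#' @export
trainReferenceModel <- function(trainSet, valSet, config = trainConfig(),
                                channels = c(8L, 16L, 32L), augment = NULL,
                                verbose = FALSE) {
  stopifnot(is(config, "TrainConfig"))
  if (length(trainSet) == 0L) stop("training set is empty")
  if (length(valSet) == 0L) stop("validation set is empty")
  means <- c(0.485, 0.456, 0.406); stds <- c(0.229, 0.224, 0.225)
  prep <- function(img) normalizeChannels(removeGreen(img), means, stds)
  asGrid <- function(m) if (is(m, "CystMask")) maskMatrix(m) else m

  valX <- lapply(valSet, function(s) prep(s$image))
  valY <- lapply(valSet, function(s) asGrid(s$mask))
  if (sum(vapply(valY, sum, 0)) == 0L)
    stop("validation set contains no cyst pixels; validation IoU is ",
         "undefined -- use a richer validation split")

  set.seed(config@seed)
  weights <- .initNet(as.integer(channels))
  state <- .adamInit(weights)
  n <- length(trainSet)
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        trainLoss = numeric(0), valIoU = numeric(0))
  best <- list(iou = -Inf, weights = weights, epoch = 0L)
  sinceImprove <- 0L

  for (epoch in seq_len(config@maxEpochs)) {
    lr <- cosineAnnealingSchedule(epoch, config@learningRate,
                                  config@t0, config@tMult)
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = config@batchSize)) {
      idx <- ord[start:min(start + config@batchSize - 1L, n)]
      grads <- NULL
      bloss <- 0
      for (i in idx) {
        s <- trainSet[[i]]
        if (!is.null(augment)) {
          aug <- augment
          aug@normalize <- FALSE
          pair <- augmentPair(s$image, CystMask(asGrid(s$mask)), aug)
          x <- prep(pair$image); y <- maskMatrix(pair$mask)
        } else {
          x <- prep(s$image); y <- asGrid(s$mask)
        }
        fwd <- .netForward(weights, x, keepCache = TRUE)
        bce <- .bceLogits(fwd$logits, y)
        bloss <- bloss + bce$loss
        g <- .netBackward(weights, fwd, bce$dz)
        grads <- if (is.null(grads)) g
                 else Map(`+`, grads, g)
      }
      grads <- lapply(grads, function(g) g / length(idx))
      upd <- .adamStep(weights, grads, state, lr)
      weights <- upd$weights; state <- upd$state
      losses <- c(losses, bloss / length(idx))
    }

    tp <- fp <- fn <- 0
    for (j in seq_along(valX)) {
      z <- .netForward(weights, valX[[j]])$logits
      pm <- stats::plogis(z) > config@threshold
      y <- valY[[j]]
      tp <- tp + sum(pm & y); fp <- fp + sum(pm & !y); fn <- fn + sum(!pm & y)
    }
    valIoU <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         trainLoss = mean(losses),
                                         valIoU = valIoU))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val IoU %.4f",
                      epoch, lr, mean(losses), valIoU))
    if (!is.na(valIoU) && valIoU > best$iou) {
      best <- list(iou = valIoU, weights = weights, epoch = epoch)
      sinceImprove <- 0L
    } else {
      sinceImprove <- sinceImprove + 1L
    }
    if (sinceImprove >= config@patience) break
  }

  backend <- new("ReferenceNet", weights = best$weights,
                 channels = as.integer(channels),
                 channelMeans = means, channelStds = stds)
  list(backend = backend, history = history, bestEpoch = best$epoch,
       bestValIoU = best$iou)
}

#' Save and load reference-network checkpoints
#'
#' Weights are serialized as an RDS list together with the architecture
#' widths and normalization statistics.
#'
#' @param backend a \linkS4class{ReferenceNet}.
#' @param path checkpoint file path.
#' @return \code{loadCheckpoint} a \linkS4class{ReferenceNet}.
#' @export
saveCheckpoint <- function(backend, path) {
  stopifnot(is(backend, "ReferenceNet"))
  saveRDS(list(weights = backend@weights, channels = backend@channels,
               channelMeans = backend@channelMeans,
               channelStds = backend@channelStds), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  new("ReferenceNet", weights = x$weights, channels = x$channels,
      channelMeans = x$channelMeans, channelStds = x$channelStds)
}
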