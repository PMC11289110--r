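#' Mute the green channel ("no-G" preprocessing)
#'
#' The relevant fluorescence signal lives in the red (tissue) and blue
#' (nuclei) channels; the green channel mostly carries noise or unrelated
#' markers. Muting sets every green value to zero while keeping a 3-channel
#' image, so backbones pretrained on RGB input remain applicable. Red and
#' blue are passed through bit-identically; the operation is idempotent.
#'
#' @param image numeric array height x width x 3.
#' @return the image with an all-zero green channel.
#' @export
removeGreen <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("removeGreen expects a 3-channel (height x width x 3) image")
  image[, , 2] <- 0
  image
}

#' Per-channel affine normalization
#'
#' Maps each channel to (x - mean) / std, with intensities and statistics
#' on the [0, 1] scale (equivalent to x/255 for 8-bit data). Defaults are
#' the standard ImageNet per-channel statistics, so normalized synthetic
#' and real images share the input distribution pretrained encoders
#' expect. The transform is invertible via \code{denormalizeChannels}.
#'
#' @param image numeric array height x width x 3, values in [0, 1].
#' @param channelMeans,channelStds per-channel statistics; stds must be
#'   positive.
#' @return a real-valued array (no longer confined to [0, 1]).
#' @export
normalizeChannels <- function(image,
                              channelMeans = c(0.485, 0.456, 0.406),
                              channelStds = c(0.229, 0.224, 0.225)) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == length(channelMeans))
  if (any(channelStds <= 0)) stop("channelStds must be positive")
  for (ch in seq_along(channelMeans))
    image[, , ch] <- (image[, , ch] - channelMeans[ch]) / channelStds[ch]
  image
}

#' @rdname normalizeChannels
#' @export
denormalizeChannels <- function(image,
                                channelMeans = c(0.485, 0.456, 0.406),
                                channelStds = c(0.229, 0.224, 0.225)) {
  for (ch in seq_along(channelMeans))
    image[, , ch] <- image[, , ch] * channelStds[ch] + channelMeans[ch]
  image
}

#' Jointly augment an image and its mask
#'
#' Applies the training-time random-transformation pipeline configured by
#' \code{\link{augmentConfig}}. Geometric transforms (horizontal flip,
#' +/-90 degree rotation -- right-angle only, so no interpolation or border
#' policy is involved) act identically on image and mask; photometric
#' transforms (brightness, contrast, gamma, CLAHE) touch only the image,
#' and the mask stays strictly binary throughout. Channel normalization,
#' when enabled, is the final step. With a seed in the config the draw is
#' reproducible.
#'
#' @param image numeric array height x width x 3, values in [0, 1].
#' @param mask a \linkS4class{CystMask} of matching size.
#' @param config an \linkS4class{AugmentConfig}.
#' @return list with \code{image} and \code{mask}.
#' @export
augmentPair <- function(image, mask, config = augmentConfig()) {
  stopifnot(is(mask, "CystMask"),
            all(dim(image)[1:2] == dim(maskMatrix(mask))))
  if (!is.na(config@seed)) set.seed(config@seed)
  grid <- maskMatrix(mask)

  if (stats::runif(1) < config@flipP) {
    image <- image[, dim(image)[2]:1, , drop = FALSE]
    grid <- grid[, ncol(grid):1, drop = FALSE]
  }
  if (stats::runif(1) < config@rotateP) {
    dir <- sample(c(-90L, 90L), 1L)
    image <- rotateRGB(image, dir)
    grid <- rotate90(grid, dir)
  }
  if (stats::runif(1) < config@brightnessP) {
    f <- stats::runif(1, 1 - config@brightnessLimit, 1 + config@brightnessLimit)
    image <- pmin(pmax(image * f, 0), 1)
  }
  if (stats::runif(1) < config@contrastP) {
    f <- stats::runif(1, 1 - config@contrastLimit, 1 + config@contrastLimit)
    m <- mean(image)
    image <- pmin(pmax((image - m) * f + m, 0), 1)
  }
  if (stats::runif(1) < config@gammaP) {
    g <- stats::runif(1, config@gammaRange[1], config@gammaRange[2]) / 100
    image <- pmin(pmax(image, 0), 1)^g
  }
  if (stats::runif(1) < config@claheP) {
    image <- .claheLuminance(image, config@claheClip)
  }
  if (config@normalize) {
    image <- normalizeChannels(image, config@channelMeans, config@channelStds)
  }
  list(image = image, mask = CystMask(grid, connectivity(mask)))
}

#' Right-angle rotation helpers
#'
#' Lossless +/-90 degree rotation of a matrix or an RGB array (positive =
#' clockwise). Used by augmentation so that no interpolation or border
#' policy is ever involved.
#'
#' @param m a matrix (\code{rotate90}) or height x width x 3 array
#'   (\code{rotateRGB}).
#' @param degrees 90 or -90.
#' @return the rotated matrix or array.
#' @export
rotate90 <- function(m, degrees) {
  if (degrees == 90L) t(m[nrow(m):1, , drop = FALSE])
  else if (degrees == -90L) t(m)[ncol(m):1, , drop = FALSE]
  else stop("only +/-90 degree rotations are supported")
}

#' @rdname rotate90
#' @export
rotateRGB <- function(m, degrees) {
  out <- array(0, c(dim(m)[2], dim(m)[1], dim(m)[3]))
  for (ch in seq_len(dim(m)[3])) out[, , ch] <- rotate90(m[, , ch], degrees)
  out
}

# CLAHE on the luminance representation (8 x 8 tile grid), channels then
# rescaled by the luminance ratio so hue is preserved
.claheLuminance <- function(image, clip) {
  y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  y2 <- EBImage::clahe(pmin(pmax(y, 0), 1), nx = 8L, ny = 8L, limit = clip)
  ratio <- ifelse(y > 1e-6, as.numeric(y2) / pmax(y, 1e-6), 1)
  for (ch in 1:3) image[, , ch] <- pmin(pmax(image[, , ch] * ratio, 0), 1)
  image
}
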