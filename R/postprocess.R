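#' Fill enclosed holes in a mask
#'
#' Cysts do not typically contain holes, so every background component that
#' is not connected to the image border is converted to foreground
#' (flood-fill from the border, complement). Border-connected background is
#' untouched and foreground never shrinks; the operation is idempotent.
#' Background components are labeled under the connectivity complementary
#' to the mask's foreground connectivity (8-connected cysts imply
#' 4-connected background, and vice versa).
#'
#' @param mask a \linkS4class{CystMask}.
#' @return the filled \linkS4class{CystMask}.
#' @examples
#' ring <- matrix(FALSE, 7, 7); ring[2:6, c(2, 6)] <- TRUE
#' ring[c(2, 6), 2:6] <- TRUE
#' nCystPixels(fillHoles(CystMask(ring)))  # the 5x5 disk: 25
#' @export
fillHoles <- function(mask) {
  stopifnot(is(mask, "CystMask"))
  grid <- maskMatrix(mask)
  bgConn <- if (connectivity(mask) == 8L) 4L else 8L
  bg <- cw_label(!grid, bgConn)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0L]
  hole <- bg > 0L & !(bg %in% border)
  grid[hole] <- TRUE
  CystMask(grid, connectivity(mask))
}

#' Apply opening or closing with a circular structuring element
#'
#' The structuring element of size \code{k} is the disc of integer pixel
#' offsets within Euclidean distance (k - 1) / 2 of the center, so
#' \code{k = 1} is the identity and an even \code{k} (half-integer radius)
#' induces the disc nested between those of \code{k - 1} and \code{k + 1}.
#' Pixels outside the image are background for both erosion and dilation;
#' each composite runs on a background-padded canvas wide enough to keep
#' intermediate dilation growth, which makes closing extensive, opening
#' anti-extensive, and both idempotent, exactly, including at image
#' borders. Closing merges over-segmented fragments of one cyst; opening
#' removes few-pixel noisy detections.
#'
#' @param mask a \linkS4class{CystMask}.
#' @param config a \linkS4class{MorphConfig} (\code{operation = "none"}
#'   returns the input unchanged).
#' @return the processed \linkS4class{CystMask}.
#' @export
applyMorphology <- function(mask, config) {
  stopifnot(is(mask, "CystMask"), is(config, "MorphConfig"))
  if (config@operation == "none" || config@k == 1L) return(mask)
  grid <- .morphRaw(maskMatrix(mask),
                    if (config@operation == "opening") "open" else "close",
                    config@k)
  CystMask(grid, connectivity(mask))
}

#' Standard postprocessing pipeline
#'
#' Flood-fill hole filling first, then the optional morphological
#' operation.
#'
#' @param mask a \linkS4class{CystMask}.
#' @param config a \linkS4class{MorphConfig}.
#' @param fill apply hole filling (default \code{TRUE}).
#' @return the postprocessed \linkS4class{CystMask}.
#' @export
postprocessMask <- function(mask, config = morphConfig("none"), fill = TRUE) {
  if (fill) mask <- fillHoles(mask)
  applyMorphology(mask, config)
}

#' Disc structuring element
#'
#' @param k element size (diameter) in pixels.
#' @return a 0/1 matrix of odd side length holding the disc of offsets
#'   within Euclidean distance (k - 1) / 2.
#' @export
discKernel <- function(k) {
  if (k < 1L) stop("k must be >= 1")
  r <- (k - 1) / 2
  ri <- floor(r)
  off <- -ri:ri
  kern <- outer(off, off, function(a, b) as.numeric(a^2 + b^2 <= r^2))
  kern
}

# erode/dilate/open/close a logical matrix with the disc of size k,
# outside-of-image treated as background; composites share one padded
# canvas so intermediate growth is retained
.morphRaw <- function(grid, op, k) {
  kern <- discKernel(k)
  r <- (nrow(kern) - 1L) / 2L
  if (r == 0L) return(grid)
  H <- nrow(grid); W <- ncol(grid)
  pad <- matrix(0, H + 2L * r, W + 2L * r)
  pad[(r + 1L):(r + H), (r + 1L):(r + W)] <- grid
  out <- switch(op,
    erode = EBImage::erode(pad, kern),
    dilate = EBImage::dilate(pad, kern),
    open = EBImage::dilate(EBImage::erode(pad, kern), kern),
    close = EBImage::erode(EBImage::dilate(pad, kern), kern),
    stop("unknown morphological operation: ", op))
  matrix(as.numeric(out) > 0.5, H + 2L * r)[(r + 1L):(r + H),
                                            (r + 1L):(r + W)]
}
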