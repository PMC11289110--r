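#' @rdname mask-accessors
#' @export
setMethod("maskMatrix", "CystMask", function(x) x@mask)

#' @rdname mask-accessors
#' @export
setMethod("connectivity", "CystMask", function(x) x@connectivity)

#' @rdname mask-accessors
#' @export
setMethod("nCystPixels", "CystMask", function(x) sum(x@mask))

#' @rdname mask-accessors
#' @export
setMethod("connectivity", "CystComponents", function(x) x@connectivity)

#' @rdname mask-accessors
#' @export
setMethod("nComponents", "CystComponents", function(x) length(x@areas))

#' @rdname mask-accessors
#' @export
setMethod("componentAreas", "CystComponents", function(x) x@areas)

#' @rdname mask-accessors
#' @export
setMethod("componentLabels", "CystComponents", function(x) x@labels)

#' @export
setMethod("dim", "CystMask", function(x) dim(x@mask))

#' Label the connected components of a mask
#'
#' Decomposes a \linkS4class{CystMask} into connected components under the
#' mask's connectivity (8-connected by default), each component realizing
#' one cyst object. Labeling is deterministic: components are numbered
#' 1..n in column-major scan order of their first pixel.
#'
#' @param mask a \linkS4class{CystMask}.
#' @return a \linkS4class{CystComponents}.
#' @examples
#' m <- CystMask(rbind(c(TRUE, FALSE), c(FALSE, TRUE)))
#' nComponents(labelComponents(m))            # 1 under 8-connectivity
#' m4 <- CystMask(maskMatrix(m), connectivity = 4)
#' nComponents(labelComponents(m4))           # 2 under 4-connectivity
#' @export
labelComponents <- function(mask) {
  stopifnot(is(mask, "CystMask"))
  lab <- cw_label(mask@mask, mask@connectivity)
  n <- max(lab, 0L)
  areas <- if (n > 0L) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  new("CystComponents", labels = lab, areas = as.integer(areas),
      connectivity = mask@connectivity)
}

#' Read and write binary mask PNGs
#'
#' Masks are stored as single-channel PNG files with 0 = background and
#' 255 = cyst. The round trip is exact: writing a mask and reading it back
#' reproduces the grid bit for bit.
#'
#' @param path file path.
#' @param mask a \linkS4class{CystMask}.
#' @param connectivity connectivity to attach to the mask read back.
#' @return \code{readMask} a \linkS4class{CystMask}; \code{writeMask} the
#'   path, invisibly.
#' @export
readMask <- function(path, connectivity = 8L) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  CystMask(arr > 0.5, connectivity = connectivity)
}

#' @rdname readMask
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "CystMask"))
  png::writePNG(matrix(as.numeric(mask@mask), nrow(mask@mask)), path)
  invisible(path)
}

#' Read and write RGB images
#'
#' Reads PNG or TIFF by extension into a height x width x 3 array with
#' values in [0, 1]; grayscale files are replicated across channels and an
#' alpha channel, if present, is dropped. \code{writeImageRGB} writes PNG.
#'
#' @param path file path (.png, .tif or .tiff).
#' @param image numeric array height x width x 3, values in [0, 1].
#' @return \code{readImageRGB} the image array; \code{writeImageRGB} the
#'   path, invisibly.
#' @export
readImageRGB <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  if (dim(arr)[3] == 1L) arr <- array(arr[, , 1L], c(dim(arr)[1:2], 3L))
  arr
}

#' @rdname readImageRGB
#' @export
writeImageRGB <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
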