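#' Read polygonal annotations from a Labelme JSON file
#'
#' Parses the Labelme dialect: a JSON object whose \code{"shapes"} array
#' holds entries with \code{"points"} (a list of [x, y] vertices) and
#' \code{"shape_type"}. Only polygon shapes are supported; vertex order is
#' preserved. Coordinates are in pixels with origin at the top-left corner.
#'
#' @param path path to a Labelme JSON file.
#' @return an \linkS4class{AnnotationSet}.
#' @seealso \code{\link{rasterizeAnnotations}}, \code{\link{writeLabelme}}
#' @export
readLabelme <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed Labelme JSON in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || is.null(obj[["shapes"]]))
    stop("malformed Labelme JSON: missing key 'shapes' in '", path, "'",
         call. = FALSE)
  imageId <- if (!is.null(obj[["imagePath"]]))
    tools::file_path_sans_ext(basename(obj[["imagePath"]]))
  else tools::file_path_sans_ext(basename(path))
  polygons <- list()
  labels <- character(0)
  for (shape in obj[["shapes"]]) {
    st <- shape[["shape_type"]]
    if (is.null(st) || !identical(st, "polygon"))
      stop("unsupported shape type '", if (is.null(st)) "<missing>" else st,
           "': only polygon shapes are supported", call. = FALSE)
    pts <- shape[["points"]]
    if (is.null(pts) || length(pts) < 3L)
      stop("polygon shape needs at least 3 points (key 'points')",
           call. = FALSE)
    m <- do.call(rbind, lapply(pts, function(p) as.numeric(unlist(p)[1:2])))
    colnames(m) <- c("x", "y")
    polygons[[length(polygons) + 1L]] <- m
    labels <- c(labels, if (is.null(shape[["label"]])) "cyst"
                else as.character(shape[["label"]]))
  }
  AnnotationSet(imageId, polygons, labels)
}

#' Write an AnnotationSet as Labelme-dialect JSON
#'
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param path output path.
#' @param imageHeight,imageWidth image size recorded in the file.
#' @param imagePath image file name recorded in the file.
#' @return the path, invisibly.
#' @export
writeLabelme <- function(annotations, path, imageHeight = NA, imageWidth = NA,
                         imagePath = NA) {
  stopifnot(is(annotations, "AnnotationSet"))
  shapes <- mapply(function(poly, lab) {
    list(label = lab,
         points = lapply(seq_len(nrow(poly)),
                         function(i) c(poly[i, 1], poly[i, 2])),
         group_id = NULL,
         shape_type = "polygon",
         flags = structure(list(), names = character(0)))
  }, annotations@polygons, annotations@labels, SIMPLIFY = FALSE)
  obj <- list(version = "5.0.0",
              flags = structure(list(), names = character(0)),
              shapes = shapes,
              imagePath = if (is.na(imagePath))
                paste0(annotations@imageId, ".png") else imagePath,
              imageData = NULL,
              imageHeight = imageHeight,
              imageWidth = imageWidth)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Rasterize polygon annotations into a binary mask
#'
#' A pixel is set when its center falls inside any polygon (even-odd rule;
#' pixel (r, c) has center (x = c + 0.5, y = r + 0.5) in 0-based
#' coordinates). Overlapping polygons union. Polygons are assumed simple
#' (non-self-intersecting), as manual annotations are, so the fill has no
#' interior holes. A polygon lying entirely outside the image raises a
#' warning and contributes nothing.
#'
#' @param annotations an \linkS4class{AnnotationSet}.
#' @param width,height mask size in pixels, matching the source image.
#' @param connectivity connectivity attached to the result.
#' @return a \linkS4class{CystMask} of the requested size.
#' @examples
#' sq <- AnnotationSet("ex", list(cbind(c(0, 0, 10, 10), c(0, 10, 10, 0))))
#' nCystPixels(rasterizeAnnotations(sq, 20, 20))  # 100
#' @export
rasterizeAnnotations <- function(annotations, width, height,
                                 connectivity = 8L) {
  stopifnot(is(annotations, "AnnotationSet"))
  width <- as.integer(width); height <- as.integer(height)
  grid <- matrix(FALSE, height, width)
  for (i in seq_along(annotations@polygons)) {
    poly <- annotations@polygons[[i]]
    if (max(poly[, 1]) <= 0 || min(poly[, 1]) >= width ||
        max(poly[, 2]) <= 0 || min(poly[, 2]) >= height) {
      warning("polygon ", i, " lies entirely outside the image bounds")
      next
    }
    grid <- grid | cw_fill_polygon(poly[, 1], poly[, 2], height, width)
  }
  CystMask(grid, connectivity = connectivity)
}
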