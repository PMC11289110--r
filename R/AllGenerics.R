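#' Mask and component accessors
#'
#' @param x a \linkS4class{CystMask} or \linkS4class{CystComponents}.
#' @return \code{maskMatrix} the logical grid; \code{connectivity} the pixel
#'   connectivity; \code{nCystPixels} the number of true pixels;
#'   \code{nComponents} the number of labeled components;
#'   \code{componentAreas} the per-component pixel counts;
#'   \code{componentLabels} the integer label matrix.
#' @name mask-accessors
NULL

#' @rdname mask-accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname mask-accessors
#' @export
setGeneric("connectivity", function(x) standardGeneric("connectivity"))

#' @rdname mask-accessors
#' @export
setGeneric("nCystPixels", function(x) standardGeneric("nCystPixels"))

#' @rdname mask-accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname mask-accessors
#' @export
setGeneric("componentAreas", function(x) standardGeneric("componentAreas"))

#' @rdname mask-accessors
#' @export
setGeneric("componentLabels", function(x) standardGeneric("componentLabels"))

#' Predict per-pixel cyst probabilities
#'
#' The backend contract: any \linkS4class{SegmentationBackend} maps an RGB
#' image (height x width x 3, values in [0, 1]) to a probability map of the
#' same height/width with values in [0, 1]. Inference is deterministic for
#' fixed weights.
#'
#' @param backend a \linkS4class{SegmentationBackend}.
#' @param image numeric array height x width x 3 in [0, 1].
#' @return numeric matrix of probabilities.
#' @export
setGeneric("predictProbabilities",
           function(backend, image) standardGeneric("predictProbabilities"))

#' Match-result accessors
#'
#' @param x a \linkS4class{CystMatch}.
#' @return \code{matchCounts} a named integer vector (DT, MS, WR);
#'   \code{matchedPairs} the matched-pair data.frame with pairwise IoUs.
#' @name match-accessors
NULL

#' @rdname match-accessors
#' @export
setGeneric("matchCounts", function(x) standardGeneric("matchCounts"))

#' @rdname match-accessors
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))
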