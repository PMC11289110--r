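#' @useDynLib cystwise, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Binary cyst mask
#'
#' A per-pixel cyst/non-cyst labeling with a declared pixel connectivity.
#' \code{CystMask} is the common currency of the pipeline: rasterized
#' annotations, binarized model output, postprocessing input and output are
#' all masks. The connectivity (4- or 8-connected) governs how true pixels
#' are grouped into cyst components; annotated cysts are compact blobs, so a
#' diagonal join should not split a cyst and 8-connectivity is the default.
#'
#' @slot mask logical matrix (rows x cols), \code{TRUE} = cyst pixel.
#' @slot connectivity integer, 4 or 8.
#' @exportClass CystMask
setClass("CystMask",
  representation(mask = "matrix", connectivity = "integer"),
  prototype(mask = matrix(logical(0), 0, 0), connectivity = 8L))

setValidity("CystMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (anyNA(object@mask)) return("mask must not contain NA")
  if (!(length(object@connectivity) == 1L &&
        object@connectivity %in% c(4L, 8L)))
    return("connectivity must be 4 or 8")
  TRUE
})

#' Construct a CystMask
#'
#' @param mask a logical matrix, or a numeric matrix which is interpreted as
#'   cyst where \code{> 0.5} (so both 0/1 and 0/255 encodings work).
#' @param connectivity pixel connectivity for component analysis, 4 or 8.
#' @return a \linkS4class{CystMask}.
#' @examples
#' m <- CystMask(matrix(c(0, 1, 1, 0), 2, 2))
#' nCystPixels(m)
#' @export
CystMask <- function(mask, connectivity = 8L) {
  if (is.numeric(mask)) {
    mask <- matrix(mask > 0.5, nrow(mask), ncol(mask))
  }
  new("CystMask", mask = mask, connectivity = as.integer(connectivity))
}

#' Labeled cyst components
#'
#' The decomposition of a \linkS4class{CystMask} into connected components,
#' each realizing one predicted or ground-truth cyst. Labels are 1..n with
#' no gaps, assigned in deterministic scan order.
#'
#' @slot labels integer matrix of per-pixel component ids, 0 = background.
#' @slot areas integer vector of component pixel counts, indexed by label.
#' @slot connectivity integer, the connectivity used for labeling.
#' @exportClass CystComponents
setClass("CystComponents",
  representation(labels = "matrix", areas = "integer", connectivity = "integer"))

setValidity("CystComponents", function(object) {
  n <- length(object@areas)
  if (n > 0 && !setequal(setdiff(unique(as.vector(object@labels)), 0L), seq_len(n)))
    return("labels must be 1..n with no gaps")
  if (sum(object@areas) != sum(object@labels > 0L))
    return("component areas must sum to the labeled pixel count")
  TRUE
})

#' Polygonal cyst annotations for one image
#'
#' Closed 2-D polygons in pixel coordinates, as produced by manual Labelme
#' annotation. Vertices are (x, y) = (col, row) with origin at the top-left
#' image corner, matching the Labelme convention.
#'
#' @slot imageId character scalar.
#' @slot polygons list of n x 2 numeric matrices (columns x, y), each with
#'   at least 3 vertices.
#' @slot labels character vector, one label per polygon (all \code{"cyst"}).
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(imageId = "character", polygons = "list", labels = "character"),
  prototype(imageId = NA_character_, polygons = list(), labels = character(0)))

setValidity("AnnotationSet", function(object) {
  if (length(object@polygons) != length(object@labels))
    return("one label per polygon required")
  for (p in object@polygons) {
    if (!is.matrix(p) || ncol(p) != 2L) return("polygons must be n x 2 matrices")
    if (nrow(p) < 3L) return("each polygon needs at least 3 vertices")
  }
  TRUE
})

#' @rdname AnnotationSet-class
#' @param imageId image identifier.
#' @param polygons list of n x 2 vertex matrices.
#' @param labels per-polygon labels, recycled if scalar.
#' @export
AnnotationSet <- function(imageId, polygons = list(), labels = "cyst") {
  labels <- rep_len(labels, length(polygons))
  new("AnnotationSet", imageId = as.character(imageId),
      polygons = polygons, labels = as.character(labels))
}

#' Synthetic scene configuration
#'
#' Parameters of the synthetic fluorescence scene generator. Defaults
#' emulate the imaged engineered-tubule preparations: 1024 x 1024
#' acquisitions, a long-tailed cyst-area distribution (log-normal
#' truncated to 30--2000 um^2, with the location parameter calibrated so
#' the truncated distribution has median ~78 um^2), and around 0--12
#' cysts per image with median 4 (Poisson with mean 4, capped at 12).
#'
#' @slot width,height canvas size in pixels.
#' @slot nCysts requested cyst count; \code{NA} samples from the per-image
#'   count distribution.
#' @slot areaMeanlog,areaSdlog log-normal parameters of the cyst-area
#'   distribution in um^2.
#' @slot areaRange truncation bounds of the area distribution, um^2.
#' @slot micronsPerPixel linear scale, um per pixel.
#' @slot bandFraction half-width of the tubule tissue band as a fraction
#'   of the image height; values of 0.5 and above make the tissue fill the
#'   frame (a close-up of the tubule wall).
#' @slot nucleiDensity expected nuclei per 1000 tissue pixels.
#' @slot tissueIntensity red-channel tissue brightness in [0, 1].
#' @slot greenNoise standard deviation of the green-channel noise.
#' @slot margin minimum pixel separation enforced between cysts.
#' @slot seed RNG seed.
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(width = "integer", height = "integer", nCysts = "integer",
    areaMeanlog = "numeric", areaSdlog = "numeric", areaRange = "numeric",
    micronsPerPixel = "numeric", bandFraction = "numeric",
    nucleiDensity = "numeric",
    tissueIntensity = "numeric", greenNoise = "numeric",
    margin = "integer", seed = "integer"))

setValidity("SceneConfig", function(object) {
  if (object@width < 32L || object@height < 32L)
    return("canvas must be at least 32 x 32")
  if (object@micronsPerPixel <= 0) return("micronsPerPixel must be positive")
  if (object@bandFraction <= 0) return("bandFraction must be positive")
  if (length(object@areaRange) != 2L || diff(object@areaRange) <= 0)
    return("areaRange must be an increasing pair")
  if (!is.na(object@nCysts) && object@nCysts < 0L)
    return("nCysts must be non-negative")
  TRUE
})

#' @rdname SceneConfig-class
#' @param width,height,nCysts,areaMeanlog,areaSdlog,areaRange,micronsPerPixel
#'   see slots.
#' @param bandFraction,nucleiDensity,tissueIntensity,greenNoise,margin,seed
#'   see slots.
#' @export
sceneConfig <- function(width = 1024L, height = 1024L, nCysts = NA_integer_,
                        areaMeanlog = log(61), areaSdlog = 0.9,
                        areaRange = c(30, 2000), micronsPerPixel = 0.5,
                        bandFraction = 0.28, nucleiDensity = 8,
                        tissueIntensity = 0.65,
                        greenNoise = 0.08, margin = 6L, seed = 1L) {
  new("SceneConfig", width = as.integer(width), height = as.integer(height),
      nCysts = as.integer(nCysts), areaMeanlog = areaMeanlog,
      areaSdlog = areaSdlog, areaRange = as.numeric(areaRange),
      micronsPerPixel = micronsPerPixel, bandFraction = bandFraction,
      nucleiDensity = nucleiDensity,
      tissueIntensity = tissueIntensity, greenNoise = greenNoise,
      margin = as.integer(margin), seed = as.integer(seed))
}

#' Synthetic scene
#'
#' Generator output: the rendered RGB image, its exact ground-truth mask,
#' and the cyst geometries (polygons approximating rotated ellipses) that
#' produced it, so known-answer tests can reason about the scene.
#'
#' @slot image numeric array height x width x 3, values in [0, 1].
#' @slot gtMask a \linkS4class{CystMask}; equals the rasterization of the
#'   stored geometries.
#' @slot geometries list with one entry per cyst: \code{polygon} (n x 2
#'   vertices), \code{center}, \code{axes}, \code{rotation}, \code{areaPx}.
#' @slot config the \linkS4class{SceneConfig} that produced the scene.
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(image = "array", gtMask = "CystMask", geometries = "list",
                 config = "SceneConfig"))

#' Mask perturbation configuration
#'
#' Controls the controlled corruption of a ground-truth mask into a
#' synthetic "prediction" whose detected/missed/wrong outcome is known in
#' advance. Random behaviour is governed by the rates; \code{dropIds},
#' \code{splitIds} and \code{spuriousExact} override the random draws so
#' exact known-answer fixtures can be constructed.
#'
#' @slot dropRate probability that a ground-truth cyst is removed.
#' @slot spuriousRate expected number of added fake blobs (Poisson mean, or
#'   the exact count when \code{spuriousExact}).
#' @slot splitRate probability that a kept cyst is split in two by a
#'   background cut.
#' @slot splitWidth width of the background cut, pixels.
#' @slot boundaryJitter erosion/dilation magnitude applied to kept
#'   components, pixels (0 disables).
#' @slot dropIds,splitIds explicit component ids to drop/split (override
#'   the rates when non-empty).
#' @slot spuriousExact logical; add exactly \code{round(spuriousRate)} blobs.
#' @slot seed RNG seed.
#' @exportClass PerturbConfig
setClass("PerturbConfig",
  representation(dropRate = "numeric", spuriousRate = "numeric",
    splitRate = "numeric", splitWidth = "integer", boundaryJitter = "integer",
    dropIds = "integer", splitIds = "integer", spuriousExact = "logical",
    seed = "integer"))

setValidity("PerturbConfig", function(object) {
  for (s in c("dropRate", "splitRate")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) return(sprintf("%s must be in [0, 1]", s))
  }
  if (object@spuriousRate < 0) return("spuriousRate must be >= 0")
  if (object@boundaryJitter < 0L) return("boundaryJitter must be >= 0")
  if (object@splitWidth < 1L || object@splitWidth > 3L)
    return("splitWidth must be 1..3 pixels")
  TRUE
})

#' @rdname PerturbConfig-class
#' @param dropRate,spuriousRate,splitRate,splitWidth,boundaryJitter see slots.
#' @param dropIds,splitIds,spuriousExact,seed see slots.
#' @export
perturbConfig <- function(dropRate = 0, spuriousRate = 0, splitRate = 0,
                          splitWidth = 2L, boundaryJitter = 0L,
                          dropIds = integer(0), splitIds = integer(0),
                          spuriousExact = FALSE, seed = 1L) {
  new("PerturbConfig", dropRate = dropRate, spuriousRate = spuriousRate,
      splitRate = splitRate, splitWidth = as.integer(splitWidth),
      boundaryJitter = as.integer(boundaryJitter),
      dropIds = as.integer(dropIds), splitIds = as.integer(splitIds),
      spuriousExact = spuriousExact, seed = as.integer(seed))
}

#' Cyst-wise match result
#'
#' The bipartite resolution of predicted vs ground-truth cyst components
#' into detected (DT), missed (MS) and wrong (WR) counts, with the matched
#' pairs and their pairwise pixel IoUs retained for downstream analyses
#' (size zones, IoU distribution).
#'
#' @slot dt,ms,wr integer counts.
#' @slot pairs data.frame with columns \code{pred}, \code{gt},
#'   \code{intersection}, \code{iou}: one row per matched (DT) pair.
#' @slot predAreas,gtAreas integer component areas in pixels.
#' @slot matchedPred,matchedGt for each pred/gt component, the id of its
#'   matched counterpart or \code{NA}.
#' @exportClass CystMatch
setClass("CystMatch",
  representation(dt = "integer", ms = "integer", wr = "integer",
    pairs = "data.frame", predAreas = "integer", gtAreas = "integer",
    matchedPred = "integer", matchedGt = "integer"))

setValidity("CystMatch", function(object) {
  if (object@dt + object@ms != length(object@gtAreas))
    return("DT + MS must equal the number of ground-truth components")
  if (object@dt + object@wr != length(object@predAreas))
    return("DT + WR must equal the number of predicted components")
  if (object@dt != nrow(object@pairs))
    return("DT must equal the number of matched pairs")
  TRUE
})

#' Morphological postprocessing configuration
#'
#' @slot operation one of \code{"none"}, \code{"opening"}, \code{"closing"}.
#' @slot k structuring-element diameter in pixels; the element is the disc
#'   of pixel offsets within Euclidean distance (k - 1) / 2 of the center,
#'   so \code{k = 1} is the identity and an even \code{k} yields the disc
#'   nested between those of \code{k - 1} and \code{k + 1}.
#' @exportClass MorphConfig
setClass("MorphConfig",
  representation(operation = "character", k = "integer"),
  prototype(operation = "none", k = 1L))

setValidity("MorphConfig", function(object) {
  if (!object@operation %in% c("none", "opening", "closing"))
    return("operation must be none, opening or closing")
  if (object@k < 1L) return("k must be >= 1")
  TRUE
})

#' @rdname MorphConfig-class
#' @param operation,k see slots.
#' @export
morphConfig <- function(operation = c("none", "opening", "closing"), k = 1L) {
  new("MorphConfig", operation = match.arg(operation), k = as.integer(k))
}

#' Cyst detection (overlap) rule
#'
#' A predicted and a ground-truth cyst are overlap candidates if they share
#' at least one pixel (the default rule) or if their pairwise pixel IoU
#' exceeds \code{tau}. The two rules coincide at \code{tau = 0}.
#'
#' @slot rule \code{"pixel"} (>= 1 shared pixel) or \code{"iou"}.
#' @slot tau IoU threshold in [0, 1), used when \code{rule = "iou"}.
#' @exportClass MatchConfig
setClass("MatchConfig",
  representation(rule = "character", tau = "numeric"),
  prototype(rule = "pixel", tau = 0))

setValidity("MatchConfig", function(object) {
  if (!object@rule %in% c("pixel", "iou")) return("rule must be pixel or iou")
  if (object@tau < 0 || object@tau >= 1) return("tau must be in [0, 1)")
  TRUE
})

#' @rdname MatchConfig-class
#' @param rule,tau see slots.
#' @export
matchConfig <- function(rule = c("pixel", "iou"), tau = 0) {
  new("MatchConfig", rule = match.arg(rule), tau = tau)
}

#' Size-zone configuration
#'
#' Six cyst-size strata on the area axis. The default boundaries are the
#' equal-cardinality sextile boundaries of the annotated-cyst area
#' distribution: 34.7, 53.3, 78.7, 120.9 and 207.5 um^2. Zones are
#' left-closed/right-open; zone 6 is unbounded above.
#'
#' @slot boundaries strictly ascending area boundaries in um^2 (length
#'   \code{nZones - 1}).
#' @slot micronsPerPixel linear scale used to convert pixel areas to um^2
#'   (area scales with its square).
#' @exportClass ZoneConfig
setClass("ZoneConfig",
  representation(boundaries = "numeric", micronsPerPixel = "numeric"),
  prototype(boundaries = c(34.7, 53.3, 78.7, 120.9, 207.5),
            micronsPerPixel = 0.5))

setValidity("ZoneConfig", function(object) {
  if (length(object@boundaries) > 0 && any(diff(object@boundaries) <= 0))
    return("boundaries must be strictly ascending")
  if (object@micronsPerPixel <= 0) return("micronsPerPixel must be positive")
  TRUE
})

#' @rdname ZoneConfig-class
#' @param boundaries,micronsPerPixel see slots.
#' @export
zoneConfig <- function(boundaries = c(34.7, 53.3, 78.7, 120.9, 207.5),
                       micronsPerPixel = 0.5) {
  new("ZoneConfig", boundaries = as.numeric(boundaries),
      micronsPerPixel = micronsPerPixel)
}

#' Training configuration for the reference network
#'
#' The training recipe applied to every backend: binary cross-entropy loss,
#' Adam at learning rate 1e-4, cosine annealing with warm restarts
#' (T0 = 10, Tmult = 2), batches of 8 images, early stopping after 10
#' epochs without validation IoU improvement, at most 100 epochs, and
#' probability binarization at 0.5.
#'
#' @slot batchSize images per optimizer step.
#' @slot learningRate initial Adam learning rate.
#' @slot t0,tMult cosine warm-restart cycle length and multiplier (epochs).
#' @slot patience early-stopping patience in epochs.
#' @slot maxEpochs maximum number of epochs.
#' @slot threshold probability binarization threshold in (0, 1).
#' @slot seed RNG seed for init and shuffling.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(batchSize = "integer", learningRate = "numeric",
    t0 = "integer", tMult = "integer", patience = "integer",
    maxEpochs = "integer", threshold = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@batchSize < 1L || object@t0 < 1L || object@tMult < 1L ||
      object@patience < 1L || object@maxEpochs < 1L ||
      object@learningRate <= 0)
    return("all training values must be positive")
  if (object@threshold <= 0 || object@threshold >= 1)
    return("threshold must be in (0, 1)")
  TRUE
})

#' @rdname TrainConfig-class
#' @param batchSize,learningRate,t0,tMult,patience,maxEpochs,threshold,seed
#'   see slots.
#' @export
trainConfig <- function(batchSize = 8L, learningRate = 1e-4, t0 = 10L,
                        tMult = 2L, patience = 10L, maxEpochs = 100L,
                        threshold = 0.5, seed = 1L) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      learningRate = learningRate, t0 = as.integer(t0),
      tMult = as.integer(tMult), patience = as.integer(patience),
      maxEpochs = as.integer(maxEpochs), threshold = threshold,
      seed = as.integer(seed))
}

#' Augmentation configuration
#'
#' The training-time random-transformation pipeline applied jointly to an
#' image and its mask: horizontal flip (p 0.5), random +/-90 degree
#' rotation (p 0.5), random brightness and contrast (limit 0.2, p 1.0,
#' multiplicative factor in [0.8, 1.2]), random gamma (limit 80--120,
#' p 0.5), CLAHE (clip limit 4, p 0.5) and normalization to reference RGB
#' channel statistics (p 1.0; ImageNet per-channel mean/std by default).
#' Geometric transforms are applied identically to image and mask;
#' photometric transforms never touch the mask.
#'
#' @slot flipP,rotateP,brightnessP,contrastP,gammaP,claheP per-transform
#'   probabilities in [0, 1].
#' @slot brightnessLimit,contrastLimit multiplicative limits (0.2 means a
#'   factor in [0.8, 1.2]).
#' @slot gammaRange gamma limits on the 100 = identity scale.
#' @slot claheClip CLAHE contrast (clip) limit.
#' @slot normalize logical, apply channel normalization as the final step.
#' @slot channelMeans,channelStds reference RGB statistics on the [0, 1]
#'   intensity scale.
#' @slot seed RNG seed (\code{NA} leaves the RNG stream untouched).
#' @exportClass AugmentConfig
setClass("AugmentConfig",
  representation(flipP = "numeric", rotateP = "numeric",
    brightnessLimit = "numeric", brightnessP = "numeric",
    contrastLimit = "numeric", contrastP = "numeric",
    gammaRange = "numeric", gammaP = "numeric",
    claheClip = "numeric", claheP = "numeric",
    normalize = "logical", channelMeans = "numeric", channelStds = "numeric",
    seed = "integer"))

setValidity("AugmentConfig", function(object) {
  probs <- c(object@flipP, object@rotateP, object@brightnessP,
             object@contrastP, object@gammaP, object@claheP)
  if (any(probs < 0 | probs > 1)) return("probabilities must be in [0, 1]")
  if (any(object@channelStds <= 0)) return("channelStds must be positive")
  TRUE
})

#' @rdname AugmentConfig-class
#' @param flipP,rotateP,brightnessLimit,brightnessP,contrastLimit,contrastP
#'   see slots.
#' @param gammaRange,gammaP,claheClip,claheP,normalize see slots.
#' @param channelMeans,channelStds,seed see slots.
#' @export
augmentConfig <- function(flipP = 0.5, rotateP = 0.5,
                          brightnessLimit = 0.2, brightnessP = 1.0,
                          contrastLimit = 0.2, contrastP = 1.0,
                          gammaRange = c(80, 120), gammaP = 0.5,
                          claheClip = 4.0, claheP = 0.5,
                          normalize = TRUE,
                          channelMeans = c(0.485, 0.456, 0.406),
                          channelStds = c(0.229, 0.224, 0.225),
                          seed = NA_integer_) {
  new("AugmentConfig", flipP = flipP, rotateP = rotateP,
      brightnessLimit = brightnessLimit, brightnessP = brightnessP,
      contrastLimit = contrastLimit, contrastP = contrastP,
      gammaRange = as.numeric(gammaRange), gammaP = gammaP,
      claheClip = claheClip, claheP = claheP, normalize = normalize,
      channelMeans = as.numeric(channelMeans),
      channelStds = as.numeric(channelStds), seed = as.integer(seed))
}

#' Segmentation backend contract
#'
#' A segmentation backend is any object that maps an RGB image (height x
#' width x 3 array with values in [0, 1]) to a per-pixel cyst probability
#' map of identical height/width with values in [0, 1], via
#' \code{\link{predictProbabilities}}. Backends own their preprocessing:
#' the reference network applies no-G muting and channel normalization
#' internally, so every backend consumes the same raw image.
#'
#' @exportClass SegmentationBackend
setClass("SegmentationBackend", representation("VIRTUAL"))

#' Red-darkness threshold baseline backend
#'
#' A training-free baseline that exploits the visual model of the images:
#' cyst lumens are dark holes in the red tissue channel. The probability
#' map is a logistic ramp on (cutoff - red intensity), confined to the
#' neighborhood of tissue. Used to exercise the evaluation pipeline
#' without any training.
#'
#' @slot cutoff red intensity below which a pixel leans cyst.
#' @slot slope logistic steepness.
#' @exportClass ThresholdBackend
setClass("ThresholdBackend", contains = "SegmentationBackend",
  representation(cutoff = "numeric", slope = "numeric"),
  prototype(cutoff = 0.3, slope = 25))

#' @rdname ThresholdBackend-class
#' @param cutoff,slope see slots.
#' @export
thresholdBackend <- function(cutoff = 0.3, slope = 25) {
  new("ThresholdBackend", cutoff = cutoff, slope = slope)
}

#' Compact encoder-decoder reference network
#'
#' A miniature of the UNet family: three resolution levels with skip
#' connections, two 3x3 convolutions per level (channel widths 8/16/32 by
#' default, about 30k parameters), 2x2 max pooling, nearest-neighbor
#' upsampling, and a 1x1 sigmoid output head. Small enough to train on a
#' single CPU while exercising the full training recipe.
#'
#' @slot weights named list of weight matrices and bias vectors.
#' @slot channels integer vector of the three encoder widths.
#' @slot channelMeans,channelStds normalization statistics applied (after
#'   no-G muting) before the network.
#' @exportClass ReferenceNet
setClass("ReferenceNet", contains = "SegmentationBackend",
  representation(weights = "list", channels = "integer",
                 channelMeans = "numeric", channelStds = "numeric"))

setMethod("show", "CystMask", function(object) {
  cat(sprintf("CystMask %d x %d, %d cyst pixels, %d-connected\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              object@connectivity))
})

setMethod("show", "CystComponents", function(object) {
  cat(sprintf("CystComponents: %d components over %d x %d (%d-connected)\n",
              length(object@areas), nrow(object@labels), ncol(object@labels),
              object@connectivity))
  if (length(object@areas))
    cat("  areas (px):", paste(utils::head(object@areas, 10), collapse = ", "),
        if (length(object@areas) > 10) "..." else "", "\n")
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet '%s': %d polygon(s)\n",
              object@imageId, length(object@polygons)))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene %d x %d: %d cyst(s), seed %d\n",
              dim(object@image)[1], dim(object@image)[2],
              length(object@geometries), object@config@seed))
})

setMethod("show", "CystMatch", function(object) {
  cat(sprintf("CystMatch: DT = %d, MS = %d, WR = %d (%d pred, %d gt)\n",
              object@dt, object@ms, object@wr,
              length(object@predAreas), length(object@gtAreas)))
})

setMethod("show", "ThresholdBackend", function(object) {
  cat(sprintf("ThresholdBackend (red-darkness baseline), cutoff %.2f\n",
              object@cutoff))
})

setMethod("show", "ReferenceNet", function(object) {
  np <- sum(vapply(object@weights, length, 0L))
  cat(sprintf("ReferenceNet: 3-level encoder-decoder, widths %s, %d parameters\n",
              paste(object@channels, collapse = "/"), np))
})
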