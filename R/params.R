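#' Construct spreading-simulator parameters
#'
#' @param filopodiaMeanUm,filopodiaSdUm filopodium length distribution (um);
#'   lengths are drawn normal and truncated to (0, \code{maxReachUm}].
#' @param maxReachUm maximal filopodial length and maximal bridgeable gap (um).
#' @param nFilopodia filopodia per platelet.
#' @param bodyRadiusUm resting platelet radius (um).
#' @param targetAreaUm2 lamellipodial spread-area budget (um^2).
#' @param maxExtentUm maximal radial extent of the fill from the centre (um).
#' @param conformFidelity per-boundary-pixel probability that the fill
#'   respects the pattern boundary, in [0,1].
#' @param offPatternSpread enable the sub-\code{fidelityScaleUm}
#'   fidelity-loss regime.
#' @param fidelityScaleUm feature scale below which conformity degrades (um).
#' @return a [SpreadingParams-class] object.
#' @examples
#' SpreadingParams()
#' SpreadingParams(nFilopodia = 12L, targetAreaUm2 = 35)
#' @export
SpreadingParams <- function(filopodiaMeanUm = 3.10, filopodiaSdUm = 0.8,
                            maxReachUm = 5.0, nFilopodia = 8L,
                            bodyRadiusUm = 1.25, targetAreaUm2 = 50,
                            maxExtentUm = 5.7, conformFidelity = 1.0,
                            offPatternSpread = FALSE, fidelityScaleUm = 5.0) {
    new("SpreadingParams",
        filopodiaMeanUm = filopodiaMeanUm, filopodiaSdUm = filopodiaSdUm,
        maxReachUm = maxReachUm, nFilopodia = as.integer(nFilopodia),
        bodyRadiusUm = bodyRadiusUm, targetAreaUm2 = targetAreaUm2,
        maxExtentUm = maxExtentUm, conformFidelity = conformFidelity,
        offPatternSpread = offPatternSpread, fidelityScaleUm = fidelityScaleUm)
}

#' Construct renderer noise parameters
#'
#' @param backgroundLevel constant background (signal units; foreground
#'   signal is 1).
#' @param photonScale counts per unit signal for Poisson shot noise; 0
#'   disables shot noise.
#' @param gaussianSd additive Gaussian noise SD (signal units).
#' @param psfSigmaUm Gaussian PSF sigma (um); 0 disables blur.
#' @param bitDepth 8 or 16.
#' @return a [NoiseParams-class] object.
#' @examples
#' NoiseParams()                       # default gentle epifluorescence model
#' NoiseParams(photonScale = 0, gaussianSd = 0,
#'             psfSigmaUm = 0, backgroundLevel = 0)  # noiseless
#' @export
NoiseParams <- function(backgroundLevel = 0.02, photonScale = 500,
                        gaussianSd = 0.02, psfSigmaUm = 0.1, bitDepth = 16L) {
    new("NoiseParams", backgroundLevel = backgroundLevel,
        photonScale = photonScale, gaussianSd = gaussianSd,
        psfSigmaUm = psfSigmaUm, bitDepth = as.integer(bitDepth))
}

#' Construct segmentation parameters
#'
#' @param thresholdMethod "otsu" or "fixed".
#' @param fixedThreshold threshold on the [0,1]-normalized channel (only for
#'   method "fixed").
#' @param minAreaUm2 minimum component area kept (um^2).
#' @param fillHoles fill holes after thresholding.
#' @param excludeBorder drop components touching the border.
#' @param connectivity 4 or 8.
#' @return a [SegmentationParams-class] object.
#' @export
SegmentationParams <- function(thresholdMethod = "otsu",
                               fixedThreshold = NA_real_, minAreaUm2 = 1.0,
                               fillHoles = TRUE, excludeBorder = TRUE,
                               connectivity = 8L) {
    new("SegmentationParams", thresholdMethod = thresholdMethod,
        fixedThreshold = fixedThreshold, minAreaUm2 = minAreaUm2,
        fillHoles = fillHoles, excludeBorder = excludeBorder,
        connectivity = as.integer(connectivity))
}

#' Construct a LabeledImage
#'
#' @param channels named list of non-negative numeric matrices of equal size.
#' @param pixelSizeUm micrometres per pixel.
#' @param provenance free-form provenance list.
#' @return a [LabeledImage-class] object.
#' @export
LabeledImage <- function(channels, pixelSizeUm, provenance = list()) {
    new("LabeledImage", channels = channels, pixelSizeUm = pixelSizeUm,
        provenance = provenance)
}

# Merge user overrides (a named list) into a params object, slot by slot.
.overrideParams <- function(params, overrides) {
    if (is.null(overrides) || !length(overrides)) return(params)
    for (nm in names(overrides)) {
        if (!nm %in% slotNames(class(params)))
            stop("unknown parameter '", nm, "' for class ", class(params))
        value <- overrides[[nm]]
        if (is(slot(params, nm), "integer")) value <- as.integer(value)
        slot(params, nm) <- value
    }
    validObject(params)
    params
}
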