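#' Render a synthetic multi-channel fluorescence image
#'
#' Per-channel model: the binary signal is blurred with a Gaussian PSF,
#' subjected to Poisson shot noise at \code{photonScale} counts per unit
#' signal, then additive Gaussian noise and a constant background, and
#' quantized to the configured bit depth. The actin channel is elevated by
#' \code{actinEdgeFactor} inside the band of platelet pixels that lie within
#' \code{bandUm} of both the platelet boundary and the pattern boundary
#' (actin enrichment at the pattern/BSA edge); the tubulin channel is
#' rendered homogeneous over the platelet.
#'
#' @param patternMask logical matrix (protein pattern).
#' @param labels integer matrix of platelet labels (0 background), same
#'   shape as \code{patternMask}.
#' @param noise a [NoiseParams-class].
#' @param channels subset of \code{c("pattern","membrane","actin","tubulin")}.
#' @param actinEdgeFactor boundary-band intensity multiplier for actin.
#' @param bandUm edge band width (um).
#' @param pixelSizeUm um per pixel.
#' @param rngSeed integer seed; required.
#' @return a [LabeledImage-class]; channel values are quantized detector
#'   numbers in \code{[0, 2^bitDepth - 1]}.
#' @export
renderImage <- function(patternMask, labels, noise = NoiseParams(),
                        channels = c("pattern", "membrane"),
                        actinEdgeFactor = 3, bandUm = 0.5,
                        pixelSizeUm = 0.1, rngSeed) {
    if (missing(rngSeed) || is.null(rngSeed) || is.na(rngSeed))
        stop("an explicit rngSeed is required (reproducibility contract)")
    known <- c("pattern", "membrane", "actin", "tubulin")
    bad <- setdiff(channels, known)
    if (length(bad))
        stop("unknown channel(s): ", paste(bad, collapse = ", "))
    needLab <- setdiff(channels, "pattern")
    if (length(needLab) && is.null(labels))
        stop("channel(s) ", paste(needLab, collapse = ", "),
             " requested without a platelet label mask")
    if ("pattern" %in% channels && is.null(patternMask))
        stop("pattern channel requested without a pattern mask")
    if (!is.null(labels) && !is.null(patternMask) &&
        !identical(dim(labels), dim(patternMask)))
        stop("pattern mask and label mask must share the same shape")

    platelet <- if (!is.null(labels)) labels > 0 else NULL
    signalOf <- function(ch) {
        switch(ch,
            pattern  = patternMask * 1.0,
            membrane = platelet * 1.0,
            tubulin  = platelet * 1.0,
            actin    = {
                band <- .edgeBandMask(platelet, patternMask, bandUm,
                                      pixelSizeUm)
                platelet * 1.0 + band * (actinEdgeFactor - 1)
            })
    }
    out <- list()
    for (k in seq_along(channels)) {
        ch <- channels[k]
        sig <- signalOf(ch)
        ceilVal <- noise@backgroundLevel +
            if (ch == "actin") max(1, actinEdgeFactor) else 1
        out[[ch]] <- .withSeed(.splitSeed(rngSeed, k, 90L),
            .applyNoise(sig, noise, pixelSizeUm, ceilVal))
    }
    LabeledImage(out, pixelSizeUm,
                 provenance = list(renderer = "plateletPattern",
                                   rngSeed = rngSeed,
                                   bitDepth = noise@bitDepth,
                                   channels = channels))
}

# band of platelet pixels near both the platelet boundary and the pattern
# boundary -- the same definition edgeIntensityRatio() measures
.edgeBandMask <- function(platelet, patternMask, bandUm, px) {
    if (is.null(patternMask)) return(platelet & FALSE)
    bandPx <- bandUm / px
    dPlat <- EBImage::imageData(EBImage::distmap(
        EBImage::Image(platelet * 1.0)))
    dPat <- EBImage::imageData(EBImage::distmap(
        EBImage::Image(patternMask * 1.0)))
    platelet & dPlat <= bandPx & dPat <= bandPx
}

.applyNoise <- function(sig, noise, px, ceilVal) {
    if (noise@psfSigmaUm > 0)
        sig <- EBImage::imageData(EBImage::gblur(
            EBImage::Image(sig), sigma = noise@psfSigmaUm / px))
    if (noise@photonScale > 0) {
        counts <- stats::rpois(length(sig), pmax(sig, 0) * noise@photonScale)
        sig <- matrix(counts / noise@photonScale, nrow(sig), ncol(sig))
    }
    if (noise@gaussianSd > 0)
        sig <- sig + matrix(stats::rnorm(length(sig), 0, noise@gaussianSd),
                            nrow(sig), ncol(sig))
    sig <- sig + noise@backgroundLevel
    dn <- (2^noise@bitDepth - 1)
    round(pmin(pmax(sig / ceilVal, 0), 1) * dn)
}
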