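#' Segment the protein-pattern channel into a binary mask
#'
#' Threshold (Otsu by default, on the [0,1]-normalized channel), fill holes,
#' keep all components.
#'
#' @param image a [LabeledImage-class] with a \code{pattern} channel.
#' @param params a [SegmentationParams-class].
#' @param channel channel name (default "pattern").
#' @return logical matrix.
#' @export
segmentPattern <- function(image, params = SegmentationParams(),
                           channel = "pattern") {
    x <- getChannel(image, channel)
    if (max(x) <= 0) stop("no pattern detected: channel is uniformly zero")
    bin <- .thresholdChannel(x, params)
    if (!any(bin)) stop("no pattern detected: nothing above threshold")
    if (params@fillHoles) bin <- .fillHoles(bin)
    bin
}

#' Segment the membrane channel into labelled platelet masks
#'
#' Threshold, fill holes, connected components at the configured
#' connectivity, drop components below \code{minAreaUm2} and (optionally)
#' components touching the border. Labels are 1..K in raster-scan order of
#' each component's first pixel; background is 0. Zero platelets is a valid
#' outcome. Touching platelets merge into one label (no watershed splitting;
#' the assay analyzes well-separated single cells).
#'
#' @param image a [LabeledImage-class] with a membrane channel.
#' @param params a [SegmentationParams-class].
#' @param channel channel name (default "membrane").
#' @return integer label matrix.
#' @export
segmentPlatelets <- function(image, params = SegmentationParams(),
                             channel = "membrane") {
    x <- getChannel(image, channel)
    px <- pixelSize(image)
    bin <- if (max(x) > 0) .thresholdChannel(x, params) else
        matrix(FALSE, nrow(x), ncol(x))
    if (params@fillHoles && any(bin)) bin <- .fillHoles(bin)
    lab <- .labelMask(bin, params@connectivity)
    if (max(lab) == 0) return(lab)
    sizes <- tabulate(lab, nbins = max(lab))
    minPx <- params@minAreaUm2 / px^2
    drop <- which(sizes < minPx)
    if (params@excludeBorder) {
        border <- unique(c(lab[1, ], lab[nrow(lab), ],
                           lab[, 1], lab[, ncol(lab)]))
        drop <- union(drop, setdiff(border, 0L))
    }
    if (length(drop)) lab[lab %in% drop] <- 0L
    # relabel 1..K in raster order
    keep <- unique(lab[lab > 0L])
    lab[lab > 0L] <- match(lab[lab > 0L], sort(keep))
    lab
}

.thresholdChannel <- function(x, params) {
    xn <- x / max(x)
    th <- if (params@thresholdMethod == "otsu")
        EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
    else params@fixedThreshold
    xn > th
}

.fillHoles <- function(bin) {
    EBImage::imageData(EBImage::fillHull(EBImage::Image(bin * 1.0))) > 0
}
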