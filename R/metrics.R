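#' On-pattern area fraction of a platelet
#'
#' Fraction of platelet pixels lying on the protein pattern, by pixel count.
#'
#' @param plateletMask logical matrix (one platelet).
#' @param patternMask logical matrix, same shape.
#' @return fraction in [0, 1].
#' @export
onPatternFraction <- function(plateletMask, patternMask) {
    if (!identical(dim(plateletMask), dim(patternMask)))
        stop("platelet and pattern masks must share the same shape")
    n <- sum(plateletMask)
    if (n == 0) stop("undefined measurement: platelet mask is empty")
    sum(plateletMask & patternMask) / n
}

#' Stripe-axis aspect ratio of a platelet
#'
#' The platelet's greatest extent along the stripe axis divided by its
#' greatest extent perpendicular to it. All mask pixel centres are projected
#' onto the axis and its perpendicular; each extent is (max - min projection)
#' plus one pixel, so a one-pixel-wide object has a nonzero width and the
#' thinnest stripes never divide by zero. Filopodial pixels count toward the
#' extents. The ratio is not constrained to be >= 1: a platelet wider than
#' long has ratio < 1.
#'
#' @param plateletMask logical matrix.
#' @param axisAngle stripe axis angle (degrees CCW from x), from the pattern
#'   ground truth or [detectStripes()].
#' @param pixelSizeUm um per pixel.
#' @return named numeric: \code{aspect_ratio}, \code{length_along_um},
#'   \code{width_perp_um}.
#' @export
aspectRatio <- function(plateletMask, axisAngle, pixelSizeUm) {
    idx <- which(plateletMask)
    if (!length(idx)) stop("undefined measurement: platelet mask is empty")
    nr <- nrow(plateletMask)
    px <- pixelSizeUm
    x <- ((idx - 1L) %/% nr + 1L - 0.5) * px
    y <- ((idx - 1L) %% nr + 1L - 0.5) * px
    al <- .alongCoord(x, y, axisAngle)
    pp <- .perpCoord(x, y, axisAngle)
    len <- (max(al) - min(al)) + px
    wid <- max((max(pp) - min(pp)) + px, px)
    c(aspect_ratio = len / wid, length_along_um = len, width_perp_um = wid)
}

#' Gap-spanning classification of a platelet
#'
#' A platelet spans when its mask intersects at least two distinct stripes.
#' The spanned gap is the separation between the touched stripes (the
#' maximum over consecutive touched pairs when more than two are touched).
#' \code{contacts_edge} is true when the mask intersects a one-pixel band
#' along any stripe boundary -- the denominator rule for the spanning
#' fraction (platelets in contact with an edge).
#'
#' @param plateletMask logical matrix.
#' @param regions stripe regions from [detectStripes()] or [stripeRegions()]
#'   (a windowed \code{idMap} of the same shape as the mask is accepted).
#' @return list: \code{spans}, \code{stripes_touched} (integer ids),
#'   \code{spanned_gap_um} (NA when not spanning), \code{contacts_edge}.
#' @export
detectSpanning <- function(plateletMask, regions) {
    if (is.null(regions$idMap) || nrow(regions$stripes) == 0)
        stop("no stripes available")
    idMap <- regions$idMap
    if (!identical(dim(plateletMask), dim(idMap)))
        stop("platelet mask and stripe id map must share the same shape")
    touched <- sort(unique(idMap[plateletMask & idMap > 0L]))
    spans <- length(touched) >= 2
    gap <- NA_real_
    if (spans) {
        gaps <- vapply(seq_len(length(touched) - 1L), function(k)
            .stripeGap(regions$stripes, touched[k], touched[k + 1L]),
            numeric(1))
        gap <- max(gaps)
    }
    band <- .patternEdgeBand(idMap)
    list(spans = spans, stripes_touched = touched, spanned_gap_um = gap,
         contacts_edge = any(plateletMask & band))
}

# one-pixel band of stripe pixels bordering background (4-neighbourhood);
# out-of-window neighbours do not count as background
.patternEdgeBand <- function(idMap) {
    fg <- idMap > 0L
    nr <- nrow(fg); nc <- ncol(fg)
    bgN <- matrix(FALSE, nr, nc)
    bgN[-1, ] <- bgN[-1, ] | !fg[-nr, ]
    bgN[-nr, ] <- bgN[-nr, ] | !fg[-1, ]
    bgN[, -1] <- bgN[, -1] | !fg[, -nc]
    bgN[, -nc] <- bgN[, -nc] | !fg[, -1]
    fg & bgN
}

#' Measure filopodia lengths from a platelet mask
#'
#' The cell body is the morphological opening of the mask with a disc of
#' radius \code{bodyOpenUm}; protrusions are the mask minus the body. Each
#' protrusion touching the body is measured as the geodesic length of its
#' pixel path from the body boundary to its tip (octile metric: 1 per
#' orthogonal step, sqrt(2) per diagonal step, plus one pixel for the tip),
#' converted to micrometres. Protrusions shorter than \code{pruneUm} are
#' discarded.
#'
#' @param plateletMask logical matrix.
#' @param pixelSizeUm um per pixel.
#' @param bodyOpenUm opening-disc radius (um); protrusions thinner than this
#'   are separated from the body.
#' @param pruneUm discard protrusions shorter than this (um).
#' @return numeric vector of filopodium lengths (um); empty for a smooth
#'   mask.
#' @export
measureFilopodia <- function(plateletMask, pixelSizeUm, bodyOpenUm = 0.8,
                             pruneUm = 0.5) {
    if (!any(plateletMask))
        stop("undefined measurement: platelet mask is empty")
    px <- pixelSizeUm
    r <- max(1L, round(bodyOpenUm / px))
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    body <- EBImage::imageData(EBImage::opening(
        EBImage::Image(plateletMask * 1.0), brush)) > 0
    prot <- plateletMask & !body
    if (!any(prot)) return(numeric(0))
    lab <- .labelMask(prot, 8L)
    nr <- nrow(prot); nc <- ncol(prot)
    # protrusion pixels 8-adjacent to the body are the measurement origin
    bodyAdj <- .dilate8(body) & prot
    lengths <- numeric(0)
    for (k in seq_len(max(lab))) {
        inset <- which(lab == k)
        seeds <- inset[bodyAdj[inset]]
        if (!length(seeds)) next      # floating debris, not a protrusion
        if (length(inset) == 1) {
            lenUm <- px
        } else {
            lenUm <- (.geodesicMax(inset, seeds, nr, nc) + 1) * px
        }
        if (lenUm >= pruneUm) lengths <- c(lengths, lenUm)
    }
    lengths
}

.dilate8 <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    out <- m
    out[-1, ] <- out[-1, ] | m[-nr, ]
    out[-nr, ] <- out[-nr, ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -nc]
    out[, -nc] <- out[, -nc] | m[, -1]
    out[-1, -1] <- out[-1, -1] | m[-nr, -nc]
    out[-nr, -nc] <- out[-nr, -nc] | m[-1, -1]
    out[-1, -nc] <- out[-1, -nc] | m[-nr, -1]
    out[-nr, -1] <- out[-nr, -1] | m[-1, -nc]
    out
}

#' Actin edge-enrichment ratio
#'
#' Mean intensity in the band of platelet pixels within \code{bandUm} of
#' both the platelet boundary and the pattern boundary, divided by the mean
#' intensity of the remaining platelet pixels. Near 1 for a homogeneous
#' channel (the tubulin control); elevated when actin accumulates at the
#' pattern/BSA edge of the cell.
#'
#' @param channel numeric intensity matrix (e.g. the actin channel).
#' @param plateletMask,patternMask logical matrices, same shape.
#' @param pixelSizeUm um per pixel.
#' @param bandUm band width (um, > 0).
#' @return ratio (dimensionless).
#' @export
edgeIntensityRatio <- function(channel, plateletMask, patternMask,
                               pixelSizeUm, bandUm = 0.5) {
    if (bandUm <= 0) stop("bandUm must be > 0")
    if (!identical(dim(channel), dim(plateletMask)) ||
        !identical(dim(channel), dim(patternMask)))
        stop("channel and masks must share the same shape")
    if (!any(plateletMask))
        stop("undefined measurement: platelet mask is empty")
    band <- .edgeBandMask(plateletMask, patternMask, bandUm, pixelSizeUm)
    interior <- plateletMask & !band
    if (!any(interior) || !any(band))
        stop("undefined measurement: band covers the whole platelet ",
             "(or no boundary band exists)")
    mInt <- mean(channel[interior])
    if (mInt <= 0)
        stop("undefined measurement: zero-intensity platelet interior")
    mean(channel[band]) / mInt
}

#' Measure every platelet in a labelled mask
#'
#' Convenience wrapper running all per-platelet metrics over a label image:
#' area, on-pattern fraction, aspect ratio, spanning/edge contact, filopodia
#' lengths, and (when an actin channel is supplied) the edge-enrichment
#' ratio.
#'
#' @param labels integer label matrix from [segmentPlatelets()] (or ground
#'   truth).
#' @param patternMask logical pattern mask, same shape.
#' @param regions stripe regions ([detectStripes()] or [stripeRegions()]).
#' @param pixelSizeUm um per pixel.
#' @param actinChannel optional intensity matrix for edge enrichment.
#' @param bandUm edge band width (um).
#' @param measureFilo run the skeleton-based filopodia measurement.
#' @param bodyOpenUm,pruneUm see [measureFilopodia()].
#' @return data.frame, one row per label (schema version in
#'   \code{attr(, "schema")}).
#' @export
measurePlatelets <- function(labels, patternMask, regions, pixelSizeUm,
                             actinChannel = NULL, bandUm = 0.5,
                             measureFilo = FALSE, bodyOpenUm = 0.8,
                             pruneUm = 0.5) {
    K <- max(labels)
    out <- list()
    for (k in seq_len(K)) {
        mask <- labels == k
        if (!any(mask)) next
        ar <- aspectRatio(mask, regions$axisAngle, pixelSizeUm)
        sp <- detectSpanning(mask, regions)
        row <- data.frame(label = k,
                          area_um2 = sum(mask) * pixelSizeUm^2,
                          on_pattern_fraction =
                              onPatternFraction(mask, patternMask),
                          length_along_um = ar[["length_along_um"]],
                          width_perp_um = ar[["width_perp_um"]],
                          aspect_ratio = ar[["aspect_ratio"]],
                          spans = sp$spans,
                          spanned_gap_um = sp$spanned_gap_um,
                          contacts_edge = sp$contacts_edge,
                          stripes_touched = paste(sp$stripes_touched,
                                                  collapse = ";"))
        if (measureFilo) {
            lens <- measureFilopodia(mask, pixelSizeUm, bodyOpenUm, pruneUm)
            row$n_filopodia_measured <- length(lens)
            row$filopodia_mean_um <- if (length(lens)) mean(lens) else NA_real_
        }
        if (!is.null(actinChannel)) {
            row$edge_actin_ratio <- tryCatch(
                edgeIntensityRatio(actinChannel, mask, patternMask,
                                   pixelSizeUm, bandUm),
                error = function(e) NA_real_)
        }
        out[[k]] <- row
    }
    res <- if (length(out)) do.call(rbind, out) else
        data.frame(label = integer(0))
    attr(res, "schema") <- "platelet_measurement_v1"
    res
}
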