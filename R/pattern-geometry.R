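#' Build a stripe pattern with varying widths at constant separation
#'
#' Models the width-series stamp: protein stripes of the given widths, in
#' order, separated by a constant gap. Stripes run along the pattern axis;
#' the first stripe starts at perpendicular offset \code{originOffsetUm}.
#'
#' @param widthsUm stripe widths in um (all > 0).
#' @param separationUm constant separation between consecutive stripes (um,
#'   >= 0).
#' @param axisAngle stripe axis angle, degrees CCW from the image x axis.
#' @param fieldUm field (height, width) in um.
#' @param pixelSizeUm um per pixel (default 0.1, resolving 0.6 um stripes).
#' @param originOffsetUm perpendicular offset of the first stripe (um).
#' @return a [StripePattern-class].
#' @examples
#' p <- makeWidthSeries(c(1, 2, 4), separationUm = 3,
#'                      fieldUm = c(30, 30))
#' stripeTable(p)         # offsets 0, 4, 9
#' @export
makeWidthSeries <- function(widthsUm, separationUm, axisAngle = 0,
                            fieldUm = c(50, 50), pixelSizeUm = 0.1,
                            originOffsetUm = 0) {
    if (!length(widthsUm) || any(widthsUm <= 0))
        stop("all stripe widths must be > 0")
    if (separationUm < 0) stop("separation must be >= 0")
    offs <- originOffsetUm +
        cumsum(c(0, utils::head(widthsUm, -1) + separationUm))
    pat <- new("StripePattern", axisAngle = axisAngle,
               stripes = data.frame(offset_um = offs, width_um = widthsUm),
               fieldUm = fieldUm, pixelSizeUm = pixelSizeUm)
    .checkPatternFits(pat)
    pat
}

#' Build a stripe pattern with constant width and varying separations
#'
#' Models the separation-series stamp: stripes of one width separated by the
#' given list of gaps.
#'
#' @param widthUm constant stripe width (um, > 0).
#' @param separationsUm gaps between consecutive stripes (um, each >= 0);
#'   an empty vector gives a single stripe.
#' @inheritParams makeWidthSeries
#' @return a [StripePattern-class].
#' @examples
#' p <- makeSeparationSeries(2, c(5, 5), fieldUm = c(30, 30))
#' stripeTable(p)         # offsets 0, 7, 14
#' @export
makeSeparationSeries <- function(widthUm, separationsUm, axisAngle = 0,
                                 fieldUm = c(50, 50), pixelSizeUm = 0.1,
                                 originOffsetUm = 0) {
    if (widthUm <= 0) stop("stripe width must be > 0")
    if (length(separationsUm) && any(separationsUm < 0))
        stop("separations must be >= 0")
    n <- length(separationsUm) + 1L
    offs <- originOffsetUm + cumsum(c(0, separationsUm + widthUm))
    pat <- new("StripePattern", axisAngle = axisAngle,
               stripes = data.frame(offset_um = offs,
                                    width_um = rep(widthUm, n)),
               fieldUm = fieldUm, pixelSizeUm = pixelSizeUm)
    .checkPatternFits(pat)
    pat
}

# total perpendicular span must fit inside the field
.checkPatternFits <- function(pattern) {
    s <- pattern@stripes
    if (!nrow(s)) return(invisible(TRUE))
    span <- max(s$offset_um + s$width_um)
    # worst-case perpendicular extent of the field over any axis angle is the
    # diagonal; for the axis-aligned cases it is the matching side
    a <- pattern@axisAngle %% 180
    lim <- if (abs(a) < 1e-6) pattern@fieldUm[1]
           else if (abs(a - 90) < 1e-6) pattern@fieldUm[2]
           else sqrt(sum(pattern@fieldUm^2))
    if (span > lim + 1e-9)
        stop("field too small for requested stripes: need a perpendicular ",
             "span of ", signif(span, 6), " um but the field allows only ",
             signif(lim, 6), " um")
    invisible(TRUE)
}

#' Rasterize a stripe pattern to a binary mask
#'
#' A pixel is on-pattern iff its centre lies inside a stripe (pixel-centre
#' point sampling, so masks are binary and pixel counts exact).
#'
#' @param pattern a [StripePattern-class].
#' @return logical matrix of size (field height / px, field width / px).
#' @examples
#' p <- makeWidthSeries(0.6, 0, fieldUm = c(5, 5), pixelSizeUm = 0.1,
#'                      originOffsetUm = 2)
#' sum(rasterizePattern(p)) / ncol(rasterizePattern(p))  # 6 px wide
#' @export
rasterizePattern <- function(pattern) {
    stopifnot(is(pattern, "StripePattern"))
    .rasterizeWindow(pattern)$mask
}

#' Map each pixel to its stripe index
#'
#' Like [rasterizePattern()] but returning the 1-based stripe index per
#' pixel (0 = background); used for spanning bookkeeping.
#'
#' @param pattern a [StripePattern-class].
#' @return integer matrix.
#' @export
stripeIdMap <- function(pattern) {
    stopifnot(is(pattern, "StripePattern"))
    .rasterizeWindow(pattern)$idMap
}

# Rasterize a rectangular pixel window of the pattern field. rows/cols are
# 1-based pixel index ranges on the full-field grid; NULL = whole field.
.rasterizeWindow <- function(pattern, rows = NULL, cols = NULL) {
    px <- pattern@pixelSizeUm
    nrF <- round(pattern@fieldUm[1] / px)
    ncF <- round(pattern@fieldUm[2] / px)
    if (is.null(rows)) rows <- c(1L, nrF)
    if (is.null(cols)) cols <- c(1L, ncF)
    rows <- c(max(1L, rows[1]), min(nrF, rows[2]))
    cols <- c(max(1L, cols[1]), min(ncF, cols[2]))
    nr <- rows[2] - rows[1] + 1L
    nc <- cols[2] - cols[1] + 1L
    i <- seq.int(rows[1], rows[2])
    j <- seq.int(cols[1], cols[2])
    y <- (i - 0.5) * px
    x <- (j - 0.5) * px
    a <- pattern@axisAngle * pi / 180
    # p = x sin(a) + y cos(a), outer over the window
    p <- outer(y * cos(a), x * sin(a), `+`)
    idMap <- matrix(.stripeIndexAt(as.vector(p), pattern@stripes), nr, nc)
    list(mask = idMap > 0L, idMap = idMap, rows = rows, cols = cols,
         originUm = c((cols[1] - 1L) * px, (rows[1] - 1L) * px),
         nrField = nrF, ncField = ncF)
}

#' Recover stripe geometry from a binary pattern mask
#'
#' Estimates the stripe axis from the second-moment (principal) axis of each
#' connected component (size-weighted circular mean over components), then
#' measures each component's width as the median perpendicular extent along
#' the stripe, reporting stripes in perpendicular-offset order together with
#' the gaps between them.
#'
#' @param patternMask logical (or 0/1) matrix with at least one on-pattern
#'   component.
#' @param pixelSizeUm um per pixel.
#' @return a list with elements \code{axisAngle} (degrees), \code{stripes}
#'   (data.frame: \code{offset_um}, \code{width_um}), \code{gaps_um},
#'   \code{idMap} (integer matrix labelling each pixel with its stripe, in
#'   offset order) and \code{pixelSizeUm}.
#' @export
detectStripes <- function(patternMask, pixelSizeUm) {
    mask <- patternMask > 0
    if (!any(mask)) stop("no pattern detected: mask is empty")
    lab <- .labelMask(mask, 8L)
    K <- max(lab)
    px <- pixelSizeUm
    idx <- which(mask)
    nr <- nrow(mask)
    iy <- ((idx - 1L) %% nr + 1L - 0.5) * px
    jx <- ((idx - 1L) %/% nr + 1L - 0.5) * px
    lb <- lab[idx]
    # principal axis per component via second central moments; orientation
    # angle theta of the major axis in (x, y_row), converted to the package
    # convention (CCW with y up => negate the row-coordinate slope)
    angles <- numeric(K); wts <- numeric(K)
    for (k in seq_len(K)) {
        sel <- lb == k
        x <- jx[sel]; y <- iy[sel]
        mxx <- stats::var(x); myy <- stats::var(y)
        mxy <- stats::cov(x, y)
        th <- 0.5 * atan2(2 * mxy, mxx - myy)   # major axis vs +x, y down
        angles[k] <- -th * 180 / pi             # convention: y up
        wts[k] <- sum(sel)
    }
    # size-weighted mean direction on the 180-degree circle
    ang2 <- angles * pi / 90
    mAng <- atan2(sum(wts * sin(ang2)), sum(wts * cos(ang2))) * 90 / pi
    axis <- mAng %% 180
    # perpendicular/along coordinates under the estimated axis
    p <- .perpCoord(jx, iy, axis)
    al <- .alongCoord(jx, iy, axis)
    offs <- numeric(K); wid <- numeric(K)
    for (k in seq_len(K)) {
        sel <- lb == k
        # median perpendicular extent across along-axis bins of one pixel
        bins <- round(al[sel] / px)
        ext <- tapply(p[sel], bins, function(v) max(v) - min(v) + px)
        wid[k] <- stats::median(ext)
        offs[k] <- min(p[sel])
    }
    ord <- order(offs)
    idMap <- matrix(0L, nrow(mask), ncol(mask))
    idMap[idx] <- match(lb, ord)
    st <- data.frame(offset_um = offs[ord], width_um = wid[ord])
    gaps <- if (K > 1) st$offset_um[-1] -
        (st$offset_um[-K] + st$width_um[-K]) else numeric(0)
    list(axisAngle = axis, stripes = st, gaps_um = gaps, idMap = idMap,
         pixelSizeUm = px)
}

#' Ground-truth stripe regions for measurement
#'
#' Converts a [StripePattern-class] into the same region structure that
#' [detectStripes()] returns, so that [detectSpanning()] can consume either
#' the measured or the ground-truth geometry.
#'
#' @param pattern a [StripePattern-class].
#' @return list as in [detectStripes()] (with exact offsets/widths).
#' @export
stripeRegions <- function(pattern) {
    stopifnot(is(pattern, "StripePattern"))
    rw <- .rasterizeWindow(pattern)
    st <- pattern@stripes
    gaps <- stripeSeparations(pattern)
    list(axisAngle = pattern@axisAngle, stripes = st, gaps_um = gaps,
         idMap = rw$idMap, pixelSizeUm = pattern@pixelSizeUm)
}

#' Read or write stripe-pattern definitions
#'
#' Patterns are stored as YAML (one document per pattern) with keys
#' \code{axis_angle_deg}, \code{field_um}, \code{pixel_size_um} and a
#' \code{stripes} list of \code{offset_um}/\code{width_um} pairs. Offsets are
#' measured perpendicular to the axis from the field origin projected on the
#' perpendicular.
#'
#' @param path file path.
#' @return \code{readPatternConfig} returns a [StripePattern-class];
#'   \code{writePatternConfig} returns \code{path} invisibly.
#' @export
readPatternConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    st <- do.call(rbind, lapply(cfg$stripes, function(s)
        data.frame(offset_um = s$offset_um, width_um = s$width_um)))
    if (is.null(st)) st <- data.frame(offset_um = numeric(0),
                                      width_um = numeric(0))
    new("StripePattern", axisAngle = cfg$axis_angle_deg,
        stripes = st, fieldUm = as.numeric(cfg$field_um),
        pixelSizeUm = cfg$pixel_size_um)
}

#' @rdname readPatternConfig
#' @param pattern a [StripePattern-class] to serialize.
#' @export
writePatternConfig <- function(pattern, path) {
    stopifnot(is(pattern, "StripePattern"))
    s <- pattern@stripes
    cfg <- list(
        axis_angle_deg = pattern@axisAngle,
        field_um = as.numeric(pattern@fieldUm),
        pixel_size_um = pattern@pixelSizeUm,
        stripes = lapply(seq_len(nrow(s)), function(k)
            list(offset_um = s$offset_um[k], width_um = s$width_um[k]))
    )
    yaml::write_yaml(cfg, path)
    invisible(path)
}

#' Write a binary or label mask as single-channel TIFF
#'
#' Binary masks are written 8-bit (0/255); label masks 16-bit.
#'
#' @param mask logical or integer matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMaskTiff <- function(mask, path) {
    if (is.logical(mask)) {
        tiff::writeTIFF(mask * 1.0, path, bits.per.sample = 8L)
    } else {
        tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
    }
    invisible(path)
}

#' Read a single-channel TIFF as a matrix
#'
#' @param path TIFF path.
#' @return numeric matrix of raw sample values.
#' @export
readImageTiff <- function(path) {
    x <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(x)) == 3) x <- x[, , 1]
    x
}
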