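#' Simulate one platelet spreading on a stripe pattern
#'
#' Static end-state generative model of filopodia-guided spreading. Rules, in
#' order: (1) \code{nFilopodia} directions are drawn uniformly and lengths
#' from a normal distribution truncated to (0, \code{maxReachUm}]; (2) a
#' probing filopodium (extended from the resting body at the seed) anchors
#' iff its tip pixel is on-pattern; (3) if none anchors and the seed is
#' off-pattern the platelet does not spread (empty mask); (4) otherwise the
#' body centre relocates to the nearest on-pattern point and lamellipodia
#' fill the nearest \code{targetAreaUm2} of the home stripe (never beyond
#' \code{maxExtentUm} from the centre); (5) filopodia then protrude their
#' full drawn length beyond the final body margin, re-anchoring at the final
#' tip; a filopodium whose tip lands on a different stripe bridges the gap
#' (a straight-line corridor plus a small lamellipodial foot on the far
#' stripe) only when that gap is at most \code{maxReachUm} -- this realizes
#' gap spanning and guarantees no platelet ever spans a wider gap.
#'
#' With \code{offPatternSpread} enabled and the home stripe narrower than
#' \code{fidelityScaleUm}, the fill admits off-pattern pixels near the
#' boundary with probability \code{(1 - conformFidelity)} tapering linearly
#' with distance (the fidelity-loss regime on thin stripes).
#'
#' @param pattern a [StripePattern-class].
#' @param seedXy numeric(2), seed point (x, y) in um; must lie in the field.
#' @param params a [SpreadingParams-class].
#' @param rngSeed integer seed; required (reproducibility contract).
#' @return list with \code{mask} (logical window matrix), \code{rows},
#'   \code{cols} (1-based pixel ranges of the window on the field grid),
#'   \code{groundTruth} (one-row data.frame) and \code{filopodia}
#'   (data.frame, one row per drawn filopodium).
#' @examples
#' p <- makeWidthSeries(10, 0, fieldUm = c(30, 30), originOffsetUm = 10)
#' s <- simulatePlatelet(p, c(15, 15), SpreadingParams(), rngSeed = 1)
#' s$groundTruth$on_pattern_fraction   # 1: fully conformal on a wide stripe
#' @export
simulatePlatelet <- function(pattern, seedXy, params = SpreadingParams(),
                             rngSeed) {
    stopifnot(is(pattern, "StripePattern"), is(params, "SpreadingParams"))
    if (missing(rngSeed) || is.null(rngSeed) || is.na(rngSeed))
        stop("an explicit rngSeed is required (reproducibility contract)")
    fld <- pattern@fieldUm
    if (seedXy[1] < 0 || seedXy[1] > fld[2] ||
        seedXy[2] < 0 || seedXy[2] > fld[1])
        stop("seed (", seedXy[1], ", ", seedXy[2], ") um lies outside the ",
             fld[1], " x ", fld[2], " um field")
    .withSeed(rngSeed, .simulatePlateletImpl(pattern, seedXy, params))
}

.simulatePlateletImpl <- function(pattern, seedXy, params) {
    px <- pattern@pixelSizeUm
    st <- pattern@stripes
    winR <- params@maxExtentUm + params@maxReachUm + 1.5
    ci <- floor(seedXy[2] / px) + 1L
    cj <- floor(seedXy[1] / px) + 1L
    w <- ceiling(winR / px)
    rw <- .rasterizeWindow(pattern, rows = c(ci - w, ci + w),
                           cols = c(cj - w, cj + w))
    idMap <- rw$idMap
    nr <- nrow(idMap); nc <- ncol(idMap)
    orig <- rw$originUm                       # (x, y) um of window corner

    pixAt <- function(xy) {
        j <- floor((xy[1] - orig[1]) / px) + 1L
        i <- floor((xy[2] - orig[2]) / px) + 1L
        if (i < 1 || i > nr || j < 1 || j > nc) return(NA_integer_)
        (j - 1L) * nr + i
    }
    stripeAt <- function(xy) {
        k <- pixAt(xy)
        if (is.na(k)) 0L else idMap[k]
    }

    n <- params@nFilopodia
    phi <- stats::runif(n, 0, 360)
    len <- if (n > 0) .rtruncnorm(n, params@filopodiaMeanUm,
                                  params@filopodiaSdUm, 0,
                                  params@maxReachUm) else numeric(0)
    dirx <- cos(phi * pi / 180)
    diry <- -sin(phi * pi / 180)

    # (1)-(2): probe from the resting body; anchor iff tip pixel on-pattern
    probeStripe <- integer(n)
    for (i in seq_len(n)) {
        tip <- seedXy + (params@bodyRadiusUm + len[i]) * c(dirx[i], diry[i])
        probeStripe[i] <- stripeAt(tip)
    }
    seedStripe <- stripeAt(seedXy)
    emptyResult <- function() {
        list(mask = matrix(FALSE, nr, nc), rows = rw$rows, cols = rw$cols,
             groundTruth = .gtRow(seedXy, NA, FALSE, 0, NA, FALSE, NA,
                                  "", 0L, n),
             filopodia = .filoTable(phi, len, rep(FALSE, n), probeStripe))
    }
    # (3): no anchor and off-pattern seed -> the platelet never spreads
    if (seedStripe == 0L && !any(probeStripe > 0L)) return(emptyResult())

    # (4): relocate to the nearest on-pattern point (analytic: stripes are
    # intervals on the perpendicular coordinate)
    centre <- seedXy
    if (seedStripe == 0L) {
        p0 <- .perpCoord(seedXy[1], seedXy[2], pattern@axisAngle)
        marg <- 0.75 * px
        best <- NULL; bestD <- Inf
        for (k in seq_len(nrow(st))) {
            lo <- st$offset_um[k] + marg
            hi <- st$offset_um[k] + st$width_um[k] - marg
            if (hi < lo) lo <- hi <- st$offset_um[k] + st$width_um[k] / 2
            pk <- min(max(p0, lo), hi)
            if (abs(pk - p0) < bestD) { bestD <- abs(pk - p0); best <- pk }
        }
        av <- .axisVectors(pattern@axisAngle)
        centre <- seedXy + (best - p0) * av$v
        if (stripeAt(centre) == 0L) {
            # numeric fallback: snap to the nearest on-pattern pixel centre
            fg <- which(idMap > 0L)
            if (!length(fg)) return(emptyResult())
            fi <- (fg - 1L) %% nr + 1L; fj <- (fg - 1L) %/% nr + 1L
            fx <- orig[1] + (fj - 0.5) * px; fy <- orig[2] + (fi - 0.5) * px
            k <- which.min((fx - seedXy[1])^2 + (fy - seedXy[2])^2)
            centre <- c(fx[k], fy[k])
        }
    }
    home <- stripeAt(centre)

    # lamellipodial fill: nearest-first pixels of the home stripe (stripes
    # are convex, so nearest-first equals geodesic growth), optionally with
    # the thin-stripe off-pattern leak
    jj <- rep(seq_len(nc), each = nr)
    ii <- rep(seq_len(nr), times = nc)
    cx <- orig[1] + (jj - 0.5) * px
    cy <- orig[2] + (ii - 0.5) * px
    d2 <- (cx - centre[1])^2 + (cy - centre[2])^2
    allowed <- as.vector(idMap == home)
    wHome <- st$width_um[home]
    if (params@offPatternSpread && params@conformFidelity < 1 &&
        wHome < params@fidelityScaleUm) {
        leakL <- params@fidelityScaleUm - wHome
        pPix <- .perpCoord(cx, cy, pattern@axisAngle)
        dPerp <- pmax(st$offset_um[home] - pPix,
                      pPix - (st$offset_um[home] + st$width_um[home]))
        cand <- as.vector(idMap == 0L) & dPerp > 0 & dPerp <= leakL
        prob <- (1 - params@conformFidelity) * (1 - dPerp / leakL)
        take <- cand & stats::runif(length(d2)) < prob
        allowed <- allowed | take
    }
    inReach <- allowed & d2 <= params@maxExtentUm^2
    aPx <- max(1L, round(params@targetAreaUm2 / px^2))
    sel <- which(inReach)
    sel <- sel[order(d2[sel])]
    body <- logical(nr * nc)
    body[utils::head(sel, aPx)] <- TRUE

    # (5): filopodia protrude beyond the final body margin; re-anchor at the
    # final tip; cross-stripe shafts bridge gaps <= maxReachUm
    mask <- body
    anchored <- logical(n)
    tipStripe <- integer(n)
    spannedGaps <- numeric(0)
    footPx <- max(1L, round(min(8, 0.2 * params@targetAreaUm2) / px^2))
    for (i in seq_len(n)) {
        dirv <- c(dirx[i], diry[i])
        tt <- seq(0, params@maxExtentUm + px, by = 0.25 * px)
        ont <- vapply(tt, function(t) {
            k <- pixAt(centre + t * dirv)
            !is.na(k) && body[k]
        }, logical(1))
        baseT <- if (any(ont)) max(tt[ont]) else 0
        base <- centre + baseT * dirv
        tip <- base + len[i] * dirv
        ts <- stripeAt(tip)
        tipStripe[i] <- ts
        ok <- ts > 0L &&
            (ts == home || .stripeGap(st, home, ts) <= params@maxReachUm)
        anchored[i] <- ok
        if (!ok) next
        shaft <- .rasterSegment(base, tip, px, nr, nc, orig)
        if (ts == home) {
            shaft <- shaft[idMap[shaft] == home]   # clip boundary strays
        } else {
            shaft <- shaft[idMap[shaft] %in% c(0L, home, ts)]
            gap <- .stripeGap(st, home, ts)
            spannedGaps <- c(spannedGaps, gap)
            # small lamellipodial foot on the far stripe around the tip
            far <- which(as.vector(idMap == ts) &
                         (cx - tip[1])^2 + (cy - tip[2])^2 <= 2.5^2)
            far <- far[order(((cx - tip[1])^2 + (cy - tip[2])^2)[far])]
            mask[utils::head(far, footPx)] <- TRUE
        }
        mask[shaft] <- TRUE
    }

    maskM <- matrix(mask, nr, nc)
    touched <- sort(unique(idMap[maskM & idMap > 0L]))
    spans <- length(spannedGaps) > 0
    gt <- .gtRow(seedXy, centre, TRUE, sum(mask) * px^2,
                 sum(mask & as.vector(idMap > 0L)) / max(1L, sum(mask)),
                 spans, if (spans) max(spannedGaps) else NA_real_,
                 paste(touched, collapse = ";"), sum(anchored), n)
    list(mask = maskM, rows = rw$rows, cols = rw$cols, groundTruth = gt,
         filopodia = .filoTable(phi, len, anchored, tipStripe))
}

.gtRow <- function(seed, centre, spread, area, frac, spans, gap, touched,
                   nAnch, nFilo) {
    data.frame(seed_x_um = seed[1], seed_y_um = seed[2],
               center_x_um = if (spread) centre[1] else NA_real_,
               center_y_um = if (spread) centre[2] else NA_real_,
               spread = spread, area_um2 = area,
               on_pattern_fraction = ifelse(spread, frac, NA_real_),
               spans = spans, spanned_gap_um = gap,
               stripes_touched = touched, n_filopodia = nFilo,
               n_anchored = nAnch, stringsAsFactors = FALSE)
}

.filoTable <- function(phi, len, anchored, tipStripe) {
    data.frame(direction_deg = phi, length_um = len, anchored = anchored,
               tip_stripe = tipStripe)
}
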