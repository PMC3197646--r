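#' @import methods
NULL

#' Parametric description of a striped protein micropattern
#'
#' A \code{StripePattern} describes a set of parallel protein stripes on a
#' rectangular field. Stripes run along the pattern axis (an angle measured
#' counterclockwise from the image x axis); each stripe is an interval on the
#' perpendicular coordinate, given by its offset from the field origin
#' (projected onto the perpendicular) and its width, both in micrometres.
#'
#' @slot axisAngle numeric(1); stripe long axis vs. the image x axis, degrees,
#'   counterclockwise.
#' @slot stripes data.frame with columns \code{offset_um} and \code{width_um},
#'   ordered by offset, non-overlapping.
#' @slot fieldUm numeric(2); field (height, width) in micrometres.
#' @slot pixelSizeUm numeric(1); micrometres per pixel used when rasterizing.
#'
#' @seealso [makeWidthSeries()], [makeSeparationSeries()], [rasterizePattern()]
#' @export
setClass("StripePattern",
    representation(
        axisAngle   = "numeric",
        stripes     = "data.frame",
        fieldUm     = "numeric",
        pixelSizeUm = "numeric"
    )
)

setValidity("StripePattern", function(object) {
    msg <- character(0)
    s <- object@stripes
    if (!all(c("offset_um", "width_um") %in% names(s)))
        msg <- c(msg, "stripes must have columns offset_um and width_um")
    else {
        if (nrow(s) > 0) {
            if (any(s$width_um <= 0))
                msg <- c(msg, "every stripe width must be > 0")
            if (is.unsorted(s$offset_um, strictly = FALSE))
                msg <- c(msg, "stripes must be sorted by offset_um")
            if (nrow(s) > 1) {
                ends <- s$offset_um[-nrow(s)] + s$width_um[-nrow(s)]
                if (any(s$offset_um[-1] < ends - 1e-9))
                    msg <- c(msg, "stripes must be non-overlapping")
            }
        }
    }
    if (length(object@pixelSizeUm) != 1 || object@pixelSizeUm <= 0)
        msg <- c(msg, "pixelSizeUm must be a single positive number")
    if (length(object@fieldUm) != 2 || any(object@fieldUm <= 0))
        msg <- c(msg, "fieldUm must be two positive numbers (height, width)")
    if (length(msg)) msg else TRUE
})

#' Generator parameters for the platelet spreading simulator
#'
#' Defaults reproduce the study conditions the simulator emulates: filopodia
#' lengths normal with mean 3.10 um and SD 0.8 um, hard-truncated to
#' (0, maxReachUm]; spreading is restricted to the protein pattern except
#' through filopodial gap corridors.
#'
#' @slot filopodiaMeanUm mean filopodium length (um).
#' @slot filopodiaSdUm SD of filopodium length (um).
#' @slot maxReachUm hard truncation of filopodial length and of the gap a
#'   platelet can bridge (um).
#' @slot nFilopodia filopodia drawn per platelet.
#' @slot bodyRadiusUm resting (unspread) platelet radius (um).
#' @slot targetAreaUm2 lamellipodial area budget (um^2).
#' @slot maxExtentUm maximal radial extent of the lamellipodial fill from the
#'   body centre (um); filopodia protrude beyond it.
#' @slot conformFidelity probability, per boundary pixel, that the fill
#'   respects the pattern boundary; 1 = perfect conformity.
#' @slot offPatternSpread logical; enable the sub-5 um fidelity-loss regime.
#' @slot fidelityScaleUm feature scale (um) below which fidelity loss applies.
#' @export
setClass("SpreadingParams",
    representation(
        filopodiaMeanUm = "numeric",
        filopodiaSdUm   = "numeric",
        maxReachUm      = "numeric",
        nFilopodia      = "integer",
        bodyRadiusUm    = "numeric",
        targetAreaUm2   = "numeric",
        maxExtentUm     = "numeric",
        conformFidelity = "numeric",
        offPatternSpread = "logical",
        fidelityScaleUm = "numeric"
    ),
    prototype(
        filopodiaMeanUm = 3.10,
        filopodiaSdUm   = 0.8,
        maxReachUm      = 5.0,
        nFilopodia      = 8L,
        bodyRadiusUm    = 1.25,
        targetAreaUm2   = 50,
        maxExtentUm     = 5.7,
        conformFidelity = 1.0,
        offPatternSpread = FALSE,
        fidelityScaleUm = 5.0
    )
)

setValidity("SpreadingParams", function(object) {
    msg <- character(0)
    lens <- c(object@filopodiaMeanUm, object@filopodiaSdUm, object@maxReachUm,
              object@bodyRadiusUm, object@targetAreaUm2, object@maxExtentUm,
              object@fidelityScaleUm)
    if (any(lens <= 0)) msg <- c(msg, "all lengths/areas must be > 0")
    if (object@filopodiaMeanUm > object@maxReachUm)
        msg <- c(msg, "filopodiaMeanUm must not exceed maxReachUm")
    if (object@conformFidelity < 0 || object@conformFidelity > 1)
        msg <- c(msg, "conformFidelity must lie in [0, 1]")
    if (object@nFilopodia < 0) msg <- c(msg, "nFilopodia must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Imaging noise model for the fluorescence renderer
#'
#' Per-channel image = blur(signal) with Poisson shot noise at
#' \code{photonScale} counts per intensity unit, plus Gaussian read noise and
#' a constant background, quantized to \code{bitDepth} bits.
#'
#' @slot backgroundLevel constant background intensity (signal units).
#' @slot photonScale counts per unit signal for shot noise; 0 disables.
#' @slot gaussianSd SD of additive Gaussian noise (signal units).
#' @slot psfSigmaUm Gaussian point-spread sigma (um); 0 disables blur.
#' @slot bitDepth 8 or 16.
#' @export
setClass("NoiseParams",
    representation(
        backgroundLevel = "numeric",
        photonScale     = "numeric",
        gaussianSd      = "numeric",
        psfSigmaUm      = "numeric",
        bitDepth        = "integer"
    ),
    prototype(
        backgroundLevel = 0.02,
        photonScale     = 500,
        gaussianSd      = 0.02,
        psfSigmaUm      = 0.1,
        bitDepth        = 16L
    )
)

setValidity("NoiseParams", function(object) {
    msg <- character(0)
    if (any(c(object@backgroundLevel, object@photonScale, object@gaussianSd,
              object@psfSigmaUm) < 0))
        msg <- c(msg, "noise parameters must be non-negative")
    if (!object@bitDepth %in% c(8L, 16L))
        msg <- c(msg, "bitDepth must be 8 or 16")
    if (length(msg)) msg else TRUE
})

#' Segmentation parameters
#'
#' @slot thresholdMethod "otsu" or "fixed".
#' @slot fixedThreshold intensity threshold on the normalized [0,1] channel;
#'   required iff \code{thresholdMethod == "fixed"}.
#' @slot minAreaUm2 drop components smaller than this (um^2).
#' @slot fillHoles fill holes in thresholded masks.
#' @slot excludeBorder drop components touching the image border.
#' @slot connectivity 4 or 8 (default 8, so 1-px diagonal filopodia stay
#'   attached to the body).
#' @export
setClass("SegmentationParams",
    representation(
        thresholdMethod = "character",
        fixedThreshold  = "numeric",
        minAreaUm2      = "numeric",
        fillHoles       = "logical",
        excludeBorder   = "logical",
        connectivity    = "integer"
    ),
    prototype(
        thresholdMethod = "otsu",
        fixedThreshold  = NA_real_,
        minAreaUm2      = 1.0,
        fillHoles       = TRUE,
        excludeBorder   = TRUE,
        connectivity    = 8L
    )
)

setValidity("SegmentationParams", function(object) {
    msg <- character(0)
    if (!object@thresholdMethod %in% c("otsu", "fixed"))
        msg <- c(msg, "thresholdMethod must be 'otsu' or 'fixed'")
    if (object@thresholdMethod == "fixed" && !is.finite(object@fixedThreshold))
        msg <- c(msg, "fixedThreshold required when thresholdMethod is 'fixed'")
    if (object@minAreaUm2 < 0) msg <- c(msg, "minAreaUm2 must be >= 0")
    if (!object@connectivity %in% c(4L, 8L))
        msg <- c(msg, "connectivity must be 4 or 8")
    if (length(msg)) msg else TRUE
})

#' Multi-channel labelled fluorescence image
#'
#' The unit every measurement consumes: named 2-D intensity rasters sharing a
#' shape, plus the physical pixel size and a provenance record.
#'
#' @slot channels named list of numeric matrices (same dimensions, >= 0).
#' @slot pixelSizeUm micrometres per pixel.
#' @slot provenance free-form list (config, seed, renderer settings).
#' @export
setClass("LabeledImage",
    representation(
        channels    = "list",
        pixelSizeUm = "numeric",
        provenance  = "list"
    ),
    prototype(provenance = list())
)

setValidity("LabeledImage", function(object) {
    msg <- character(0)
    ch <- object@channels
    if (length(ch) == 0) msg <- c(msg, "at least one channel required")
    if (is.null(names(ch)) || any(names(ch) == ""))
        msg <- c(msg, "channels must be named")
    dims <- lapply(ch, dim)
    if (length(ch) > 1 && !all(vapply(dims[-1], identical, logical(1), dims[[1]])))
        msg <- c(msg, "all channels must share the same dimensions")
    if (any(vapply(ch, function(m) any(m < 0), logical(1))))
        msg <- c(msg, "intensities must be non-negative")
    if (length(object@pixelSizeUm) != 1 || object@pixelSizeUm <= 0)
        msg <- c(msg, "pixelSizeUm must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Per-geometry aggregate curve with optional exponential fit
#'
#' One point per geometry condition (stripe width or separation): mean, SEM
#' (sample SD / sqrt(n)), n, and the per-group maximum. After
#' [fitExponential()], also the fitted model id, its parameters and
#' diagnostics.
#'
#' @slot x geometry values (um).
#' @slot mean,sem,maxObserved per-group statistics.
#' @slot n per-group counts.
#' @slot statistic which per-platelet statistic was aggregated.
#' @slot groupKey "width" or "separation".
#' @slot model fitted model id (empty until fitted).
#' @slot fitParams named numeric fit parameters.
#' @slot fitInfo list: rss, converged, message.
#' @export
setClass("GeometryCurve",
    representation(
        x           = "numeric",
        mean        = "numeric",
        sem         = "numeric",
        n           = "integer",
        maxObserved = "numeric",
        statistic   = "character",
        groupKey    = "character",
        model       = "character",
        fitParams   = "numeric",
        fitInfo     = "list"
    ),
    prototype(model = character(0), fitParams = numeric(0), fitInfo = list())
)

setValidity("GeometryCurve", function(object) {
    msg <- character(0)
    k <- length(object@x)
    if (length(object@mean) != k || length(object@sem) != k ||
        length(object@n) != k || length(object@maxObserved) != k)
        msg <- c(msg, "x, mean, sem, n, maxObserved must have equal length")
    if (k > 0 && any(object@n < 1))
        msg <- c(msg, "every retained group needs n >= 1")
    if (length(msg)) msg else TRUE
})
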