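#' Accessor generics
#'
#' Small accessor family for the package's S4 classes; use these rather than
#' reaching into slots.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("axisAngle", function(object) standardGeneric("axisAngle"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("stripeTable", function(object) standardGeneric("stripeTable"))

#' @rdname accessors
#' @export
setGeneric("stripeWidths", function(object) standardGeneric("stripeWidths"))

#' @rdname accessors
#' @export
setGeneric("stripeSeparations",
    function(object) standardGeneric("stripeSeparations"))

#' @rdname accessors
#' @export
setGeneric("fieldDim", function(object) standardGeneric("fieldDim"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' Extract one channel of a LabeledImage
#' @param object a [LabeledImage-class].
#' @param name channel name.
#' @return numeric matrix.
#' @export
setGeneric("getChannel", function(object, name) standardGeneric("getChannel"))

#' @rdname accessors
#' @export
setGeneric("curveData", function(object) standardGeneric("curveData"))

#' @rdname accessors
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))

#' @describeIn StripePattern stripe axis angle (degrees CCW from x).
#' @param object a \code{StripePattern}.
#' @export
setMethod("axisAngle", "StripePattern", function(object) object@axisAngle)

#' @describeIn StripePattern pixel size in um/px.
#' @export
setMethod("pixelSize", "StripePattern", function(object) object@pixelSizeUm)

#' @describeIn StripePattern stripe table (offset_um, width_um).
#' @export
setMethod("stripeTable", "StripePattern", function(object) object@stripes)

#' @describeIn StripePattern stripe widths (um).
#' @export
setMethod("stripeWidths", "StripePattern",
    function(object) object@stripes$width_um)

#' @describeIn StripePattern separations between consecutive stripes (um).
#' @export
setMethod("stripeSeparations", "StripePattern", function(object) {
    s <- object@stripes
    if (nrow(s) < 2) return(numeric(0))
    s$offset_um[-1] - (s$offset_um[-nrow(s)] + s$width_um[-nrow(s)])
})

#' @describeIn StripePattern field (height, width) in um.
#' @export
setMethod("fieldDim", "StripePattern", function(object) object@fieldUm)

#' @describeIn LabeledImage pixel size in um/px.
#' @param object a \code{LabeledImage}.
#' @export
setMethod("pixelSize", "LabeledImage", function(object) object@pixelSizeUm)

#' @describeIn LabeledImage channel names.
#' @export
setMethod("channelNames", "LabeledImage",
    function(object) names(object@channels))

#' @describeIn LabeledImage extract one channel matrix.
#' @param name channel name.
#' @export
setMethod("getChannel", "LabeledImage", function(object, name) {
    if (!name %in% names(object@channels))
        stop("channel '", name, "' not present (have: ",
             paste(names(object@channels), collapse = ", "), ")")
    object@channels[[name]]
})

#' @describeIn GeometryCurve the per-group statistics as a data.frame.
#' @param object a \code{GeometryCurve}.
#' @export
setMethod("curveData", "GeometryCurve", function(object) {
    data.frame(x = object@x, mean = object@mean, sem = object@sem,
               n = object@n, max_observed = object@maxObserved)
})

#' @describeIn GeometryCurve named fitted parameters (empty if unfitted).
#' @export
setMethod("fitParams", "GeometryCurve", function(object) object@fitParams)

setMethod("show", "StripePattern", function(object) {
    s <- object@stripes
    cat("StripePattern:", nrow(s), "stripe(s), axis",
        object@axisAngle, "deg\n")
    cat("  field", paste(object@fieldUm, collapse = " x "), "um at",
        object@pixelSizeUm, "um/px\n")
    if (nrow(s)) {
        cat("  widths (um):", paste(signif(s$width_um, 4), collapse = ", "),
            "\n")
        sep <- stripeSeparations(object)
        if (length(sep))
            cat("  separations (um):", paste(signif(sep, 4), collapse = ", "),
                "\n")
    }
})

setMethod("show", "LabeledImage", function(object) {
    d <- dim(object@channels[[1]])
    cat("LabeledImage:", d[1], "x", d[2], "px at", object@pixelSizeUm,
        "um/px\n  channels:", paste(names(object@channels), collapse = ", "),
        "\n")
})

setMethod("show", "GeometryCurve", function(object) {
    cat("GeometryCurve:", object@statistic, "by", object@groupKey, "(",
        length(object@x), "groups )\n")
    if (length(object@model)) {
        cat("  model:", object@model, " params:",
            paste(names(object@fitParams), signif(object@fitParams, 5),
                  sep = "=", collapse = ", "), "\n")
    }
})

setMethod("show", "SpreadingParams", function(object) {
    cat("SpreadingParams: filopodia", object@filopodiaMeanUm, "+/-",
        object@filopodiaSdUm, "um (reach <=", object@maxReachUm, "um), n =",
        object@nFilopodia, "\n  body r", object@bodyRadiusUm,
        "um, area budget", object@targetAreaUm2, "um^2, max extent",
        object@maxExtentUm, "um\n  conformity", object@conformFidelity,
        if (object@offPatternSpread) "(off-pattern leak enabled)" else "",
        "\n")
})
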