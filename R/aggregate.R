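#' Aggregate per-platelet measurements by geometry condition
#'
#' Per-group mean, SEM (sample SD / sqrt(n)), n and maximum of one
#' per-platelet statistic, grouped by stripe width or separation. For the
#' spanning statistic the group value is the spanning proportion with
#' binomial SEM sqrt(p(1-p)/n), and the denominator is restricted to
#' platelets in contact with a stripe edge.
#'
#' Groups with a single member are retained with SEM 0 and flagged in
#' \code{fitInfo$singleton_groups} of the returned curve.
#'
#' @param measurements data.frame with columns \code{condition_value} and
#'   the requested statistic (from [measureDataset()] or
#'   [measurePlatelets()] plus a condition column).
#' @param groupKey "width" or "separation" (labelling only).
#' @param statistic one of \code{"on_pattern_fraction"},
#'   \code{"aspect_ratio"}, \code{"spans"}.
#' @return a [GeometryCurve-class] (unfitted).
#' @export
aggregateByGroup <- function(measurements,
                             groupKey = c("width", "separation"),
                             statistic = c("on_pattern_fraction",
                                           "aspect_ratio", "spans")) {
    groupKey <- match.arg(groupKey)
    statistic <- match.arg(statistic)
    if (!nrow(measurements)) stop("empty measurement table")
    df <- measurements
    if (statistic == "spans") {
        if ("contacts_edge" %in% names(df)) df <- df[df$contacts_edge, ]
        if (!nrow(df))
            stop("no platelets in contact with an edge (empty denominator)")
        df$.y <- as.numeric(df$spans)
    } else {
        df$.y <- df[[statistic]]
    }
    df <- df[is.finite(df$.y), ]
    if (!nrow(df)) stop("no finite values for statistic ", statistic)
    xs <- sort(unique(df$condition_value))
    agg <- lapply(xs, function(v) {
        y <- df$.y[df$condition_value == v]
        n <- length(y)
        m <- mean(y)
        sem <- if (statistic == "spans") sqrt(m * (1 - m) / n)
               else if (n > 1) stats::sd(y) / sqrt(n) else 0
        c(m = m, sem = sem, n = n, mx = max(y))
    })
    a <- do.call(rbind, agg)
    singles <- xs[a[, "n"] == 1]
    new("GeometryCurve", x = xs, mean = a[, "m"], sem = a[, "sem"],
        n = as.integer(a[, "n"]), maxObserved = a[, "mx"],
        statistic = statistic, groupKey = groupKey,
        fitInfo = if (length(singles))
            list(singleton_groups = singles) else list())
}

#' Fit an exponential trend to a geometry curve
#'
#' Unweighted least squares to the group means (fits to average data).
#' Models, with x the geometry value in um:
#' \describe{
#'   \item{rise_to_one}{y = 1 - a exp(-x/b) (on-pattern fraction vs width).}
#'   \item{decay_to_one}{y = 1 + a exp(-x/b) (aspect ratio vs width).}
#'   \item{decay_to_zero}{y = c exp(-x/b) (spanning fraction vs
#'     separation).}
#' }
#' The asymptote (1 or 0) is fixed, not fitted. Initial values: b from a
#' log-linear regression of |y - asymptote| on x; a (or c) from its
#' intercept. Non-convergence and degenerate cases (e.g. constant y at the
#' asymptote) are flagged in \code{fitInfo}, never silently replaced.
#'
#' @param curve a [GeometryCurve-class] from [aggregateByGroup()].
#' @param model one of \code{"rise_to_one"}, \code{"decay_to_one"},
#'   \code{"decay_to_zero"}.
#' @return the curve with \code{model}, \code{fitParams} and \code{fitInfo}
#'   (rss, converged, degenerate, message) filled in.
#' @export
fitExponential <- function(curve, model = c("rise_to_one", "decay_to_one",
                                            "decay_to_zero")) {
    model <- match.arg(model)
    stopifnot(is(curve, "GeometryCurve"))
    x <- curve@x; y <- curve@mean
    if (length(x) < 3) stop("need at least 3 groups to fit")
    asym <- if (model == "decay_to_zero") 0 else 1
    r <- abs(y - asym)
    info <- curve@fitInfo
    if (max(r) < 1e-8) {
        # constant at the asymptote: amplitude 0, rate unidentifiable
        curve@model <- model
        curve@fitParams <- if (model == "decay_to_zero")
            c(c = 0, b = NA_real_) else c(a = 0, b = NA_real_)
        info$rss <- sum((y - asym)^2)
        info$converged <- TRUE
        info$degenerate <- TRUE
        info$message <- "constant at asymptote; rate not identifiable"
        curve@fitInfo <- info
        return(curve)
    }
    pos <- r > 1e-12
    ll <- stats::lm(log(r[pos]) ~ x[pos])
    b0 <- unname(-1 / min(stats::coef(ll)[2], -1e-6))
    a0 <- unname(exp(stats::coef(ll)[1]))
    sgn <- if (model == "decay_to_one") sign(stats::median(y - asym)) else 1
    fml <- switch(model,
        rise_to_one  = y ~ 1 - a * exp(-x / b),
        decay_to_one = y ~ 1 + a * exp(-x / b),
        decay_to_zero = y ~ cc * exp(-x / b))
    start <- if (model == "decay_to_zero") list(cc = a0, b = b0)
             else list(a = sgn * a0, b = b0)
    dat <- data.frame(x = x, y = y)
    fit <- tryCatch(
        minpack.lm::nlsLM(fml, data = dat, start = start,
                          control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
        error = function(e) e)
    curve@model <- model
    if (inherits(fit, "error")) {
        curve@fitParams <- stats::setNames(rep(NA_real_, 2),
            if (model == "decay_to_zero") c("c", "b") else c("a", "b"))
        info$converged <- FALSE
        info$degenerate <- FALSE
        info$message <- conditionMessage(fit)
        curve@fitInfo <- info
        return(curve)
    }
    cf <- stats::coef(fit)
    names(cf)[names(cf) == "cc"] <- "c"
    curve@fitParams <- cf
    info$rss <- sum(stats::residuals(fit)^2)
    info$converged <- fit$convInfo$isConv %||% TRUE
    info$degenerate <- FALSE
    info$message <- "ok"
    curve@fitInfo <- info
    curve
}

#' Predict from a fitted geometry curve
#'
#' @param curve a fitted [GeometryCurve-class].
#' @param x geometry values (um).
#' @return predicted statistic values.
#' @export
predictCurve <- function(curve, x) {
    if (!length(curve@model)) stop("curve has no fitted model")
    p <- curve@fitParams
    switch(curve@model,
        rise_to_one  = 1 - p[["a"]] * exp(-x / p[["b"]]),
        decay_to_one = 1 + p[["a"]] * exp(-x / p[["b"]]),
        decay_to_zero = p[["c"]] * exp(-x / p[["b"]]))
}

#' Largest separation spanned by any platelet
#'
#' The largest gap value among spanning platelets; 0 (flagged) when no
#' platelet spans anywhere. Accepts measured or ground-truth tables: rows
#' need \code{spans} and a gap column (\code{spanned_gap_um}).
#'
#' @param measurements data.frame with \code{spans} and
#'   \code{spanned_gap_um}.
#' @return numeric(1) with attribute \code{no_spanning} = TRUE when 0 for
#'   lack of any spanning event.
#' @export
spanningThreshold <- function(measurements) {
    sp <- measurements[measurements$spans %in% TRUE, , drop = FALSE]
    sp <- sp[is.finite(sp$spanned_gap_um), , drop = FALSE]
    if (!nrow(sp)) {
        out <- 0
        attr(out, "no_spanning") <- TRUE
        return(out)
    }
    max(sp$spanned_gap_um)
}

#' Plot a geometry curve
#'
#' Publication-style plot: group means as points with SEM error bars, the
#' fitted exponential as a line, and per-group maxima as crosses.
#'
#' @param curve a [GeometryCurve-class].
#' @param showMax draw per-group maxima as "+".
#' @param xlab,ylab,main usual graphics labels.
#' @param ... passed to [plot()].
#' @return invisibly, the curve.
#' @export
plotGeometryCurve <- function(curve, showMax = FALSE, xlab = NULL,
                              ylab = NULL, main = NULL, ...) {
    xlab <- xlab %||% paste(curve@groupKey, "(um)")
    ylab <- ylab %||% curve@statistic
    ylim <- range(c(curve@mean - curve@sem, curve@mean + curve@sem,
                    if (showMax) curve@maxObserved), finite = TRUE)
    graphics::plot(curve@x, curve@mean, pch = 16, xlab = xlab, ylab = ylab,
                   main = main, ylim = ylim, ...)
    hasBar <- curve@sem > 0
    if (any(hasBar))
        graphics::arrows(curve@x[hasBar],
                         (curve@mean - curve@sem)[hasBar], curve@x[hasBar],
                         (curve@mean + curve@sem)[hasBar], angle = 90,
                         code = 3, length = 0.03)
    if (showMax)
        graphics::points(curve@x, curve@maxObserved, pch = 3)
    if (length(curve@model) && all(is.finite(curve@fitParams))) {
        xx <- seq(min(curve@x), max(curve@x), length.out = 200)
        graphics::lines(xx, predictCurve(curve, xx))
    }
    invisible(curve)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
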