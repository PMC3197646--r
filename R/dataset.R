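#' Generate a synthetic micropattern spreading experiment
#'
#' Drives [simulatePlatelet()] (and optionally [renderImage()]) over a series
#' of geometry conditions, producing ground-truth tables, per-platelet masks
#' and, when an output directory is given, TIFF images plus a manifest.
#'
#' The configuration is a list (or YAML file) with fields:
#' \describe{
#'   \item{series}{"width" (stripe widths vary, constant separation) or
#'     "separation" (constant width, separations vary).}
#'   \item{widths_um / separation_um}{width series: vector of widths and the
#'     constant separation (default 10).}
#'   \item{width_um / separations_um}{separation series: the constant width
#'     (default 10) and the vector of separations.}
#'   \item{n_per_condition}{platelets per geometry condition.}
#'   \item{n_stripes}{stripes per condition pattern (default 3 for width,
#'     2 for separation series).}
#'   \item{seed_placement}{"on_stripe" (uniform over a stripe),
#'     "edge_adjacent" (within 1 um of a gap-facing stripe edge; the
#'     spanning-assay denominator), or "random" (uniform over the field,
#'     possibly off-pattern).}
#'   \item{axis_angle_deg}{0 or 90 for generated fields (default 0).}
#'   \item{pixel_size_um}{default 0.1.}
#'   \item{render}{render fluorescence images (default FALSE in memory,
#'     TRUE when \code{outDir} is given).}
#'   \item{channels, actin_edge_factor}{renderer settings.}
#'   \item{spreading, noise}{named lists of [SpreadingParams()] /
#'     [NoiseParams()] overrides.}
#' }
#'
#' @param config list or path to a YAML config.
#' @param rngSeed integer; all randomness flows from it through a
#'   counter-based splitting scheme, so per-platelet results are
#'   order-independent.
#' @param outDir optional output directory (must not exist unless
#'   \code{force}); images, CSVs and a manifest are written there.
#' @param keepMasks keep sparse per-platelet masks in the returned object
#'   (needed by [measureDataset()]).
#' @param force overwrite an existing \code{outDir}.
#' @return (invisibly when writing) a list with \code{groundTruth},
#'   \code{filopodia}, \code{conditions} (patterns and condition values),
#'   \code{masks} (sparse windows), \code{images} (if rendered in memory)
#'   and \code{manifest}.
#' @export
generateDataset <- function(config, rngSeed, outDir = NULL,
                            keepMasks = TRUE, force = FALSE) {
    if (missing(rngSeed) || is.null(rngSeed) || is.na(rngSeed))
        stop("an explicit rngSeed is required (reproducibility contract)")
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- .datasetConfig(config)
    if (!is.null(outDir)) {
        if (dir.exists(outDir) && !force &&
            length(list.files(outDir)))
            stop("output directory exists and is not empty; use force = TRUE")
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    }
    conds <- .datasetConditions(cfg)
    sparams <- .overrideParams(SpreadingParams(), cfg$spreading)
    nparams <- .overrideParams(NoiseParams(), cfg$noise)

    gt <- list(); filo <- list(); masks <- list(); images <- list()
    if (cfg$n_per_condition == 0)
        warning("zero platelets requested; writing manifest only")
    gid <- 0L
    for (ci in seq_along(conds)) {
        cond <- conds[[ci]]
        for (k in seq_len(cfg$n_per_condition)) {
            gid <- gid + 1L
            seedXy <- .withSeed(.splitSeed(rngSeed, gid, 1L),
                .placeSeed(cond, cfg, k))
            sim <- simulatePlatelet(cond$pattern, seedXy, sparams,
                                    rngSeed = .splitSeed(rngSeed, gid, 2L))
            row <- cbind(platelet_id = gid, condition_key = cfg$series,
                         condition_value = cond$value, sim$groundTruth)
            gt[[gid]] <- row
            if (nrow(sim$filopodia))
                filo[[gid]] <- cbind(platelet_id = gid,
                                     condition_value = cond$value,
                                     sim$filopodia)
            if (keepMasks || cfg$render)
                masks[[gid]] <- list(idx = which(sim$mask),
                                     nr = nrow(sim$mask),
                                     nc = ncol(sim$mask),
                                     rows = sim$rows, cols = sim$cols,
                                     cond = ci)
        }
    }
    groundTruth <- if (length(gt)) do.call(rbind, gt) else
        .gtRow(c(NA, NA), NA, FALSE, 0, NA, FALSE, NA, "", 0L, 0L)[0, ]
    filopodia <- if (length(filo)) do.call(rbind, filo) else
        data.frame(platelet_id = integer(0))

    if (cfg$render) {
        groundTruth$label <- NA_integer_
        for (ci in seq_along(conds)) {
            asm <- .assembleLabels(conds[[ci]], masks, ci)
            lab <- asm$lab
            groundTruth$label[match(asm$map$platelet_id,
                                    groundTruth$platelet_id)] <- asm$map$label
            img <- renderImage(rasterizePattern(conds[[ci]]$pattern), lab,
                               noise = nparams, channels = cfg$channels,
                               actinEdgeFactor = cfg$actin_edge_factor,
                               pixelSizeUm = cfg$pixel_size_um,
                               rngSeed = .splitSeed(rngSeed, ci, 3L))
            conds[[ci]]$labels <- lab
            images[[ci]] <- img
        }
    }
    manifest <- list(config = cfg, rngSeed = rngSeed,
                     package_version = as.character(
                         utils::packageVersion("plateletPattern")),
                     n_platelets = gid,
                     conditions = vapply(conds, `[[`, numeric(1), "value"))
    ds <- list(groundTruth = groundTruth, filopodia = filopodia,
               conditions = conds, masks = if (keepMasks) masks else list(),
               images = images, manifest = manifest, config = cfg)
    if (!is.null(outDir)) {
        .writeDataset(ds, outDir, nparams)
        return(invisible(ds))
    }
    ds
}

.datasetConfig <- function(config) {
    cfg <- config
    if (is.null(cfg$series)) stop("config needs a 'series' field")
    cfg$series <- match.arg(cfg$series, c("width", "separation"))
    if (cfg$series == "width") {
        if (is.null(cfg$widths_um)) stop("width series needs widths_um")
        if (is.null(cfg$separation_um)) cfg$separation_um <- 10
        if (is.null(cfg$n_stripes)) cfg$n_stripes <- 3L
        if (is.null(cfg$seed_placement)) cfg$seed_placement <- "on_stripe"
    } else {
        if (is.null(cfg$separations_um))
            stop("separation series needs separations_um")
        if (is.null(cfg$width_um)) cfg$width_um <- 10
        if (is.null(cfg$n_stripes)) cfg$n_stripes <- 2L
        if (is.null(cfg$seed_placement)) cfg$seed_placement <- "edge_adjacent"
    }
    cfg$seed_placement <- match.arg(cfg$seed_placement,
                                    c("on_stripe", "edge_adjacent", "random"))
    if (is.null(cfg$n_per_condition)) cfg$n_per_condition <- 30L
    if (is.null(cfg$axis_angle_deg)) cfg$axis_angle_deg <- 0
    if (!cfg$axis_angle_deg %in% c(0, 90))
        stop("generated fields support axis angles 0 or 90")
    if (is.null(cfg$pixel_size_um)) cfg$pixel_size_um <- 0.1
    if (is.null(cfg$render)) cfg$render <- FALSE
    if (is.null(cfg$channels))
        cfg$channels <- c("pattern", "membrane", "actin", "tubulin")
    if (is.null(cfg$actin_edge_factor)) cfg$actin_edge_factor <- 3
    cfg
}

# one pattern per condition; the perpendicular margin keeps every platelet
# window inside the field, the along extent depends on the layout
.datasetConditions <- function(cfg) {
    margin <- 12
    spacing <- 13
    values <- if (cfg$series == "width") cfg$widths_um else cfg$separations_um
    lapply(values, function(v) {
        if (cfg$series == "width") {
            widths <- rep(v, cfg$n_stripes); sep <- cfg$separation_um
        } else {
            widths <- rep(cfg$width_um, cfg$n_stripes)
            sep <- v
        }
        span <- sum(widths) + sep * (length(widths) - 1)
        perp <- span + 2 * margin
        nslots <- ceiling(cfg$n_per_condition / cfg$n_stripes)
        along <- if (cfg$render) 2 * 6 + max(1, nslots) * spacing else 40
        fld <- if (cfg$axis_angle_deg == 0) c(perp, along) else c(along, perp)
        pat <- makeWidthSeries(widths, sep, axisAngle = cfg$axis_angle_deg,
                               fieldUm = fld,
                               pixelSizeUm = cfg$pixel_size_um,
                               originOffsetUm = margin)
        list(value = v, pattern = pat, spacing = spacing, margin = margin)
    })
}

# seed placement for platelet k of a condition (called inside .withSeed)
.placeSeed <- function(cond, cfg, k) {
    pat <- cond$pattern
    st <- pat@stripes
    ns <- nrow(st)
    px <- pat@pixelSizeUm
    fld <- pat@fieldUm
    alongMax <- if (cfg$axis_angle_deg == 0) fld[2] else fld[1]
    if (cfg$render) {
        stripe <- (k - 1L) %% ns + 1L
        slot <- (k - 1L) %/% ns
        a <- 6 + (slot + 0.5) * cond$spacing + stats::runif(1, -1.5, 1.5)
    } else {
        stripe <- sample.int(ns, 1)
        a <- stats::runif(1, 2, alongMax - 2)
    }
    w <- st$width_um[stripe]
    p <- switch(cfg$seed_placement,
        on_stripe = {
            if (w > 2 * px)
                st$offset_um[stripe] + px + stats::runif(1) * (w - 2 * px)
            else st$offset_um[stripe] + w / 2
        },
        edge_adjacent = {
            # pick a gap-facing edge of the stripe and sit within 1 um of it
            edges <- c(if (stripe > 1) "lo", if (stripe < ns) "hi")
            e <- if (length(edges) == 1) edges else sample(edges, 1)
            d <- stats::runif(1, 0.5 * px, min(1, w / 2))
            if (e == "hi") st$offset_um[stripe] + w - d
            else st$offset_um[stripe] + d
        },
        random = {
            perpMax <- if (cfg$axis_angle_deg == 0) fld[1] else fld[2]
            stats::runif(1, 0, perpMax)
        })
    if (cfg$axis_angle_deg == 0) c(a, p) else c(p, a)
}

# paste the sparse platelet masks of one condition into a field-sized
# integer label canvas; returns the canvas plus the platelet_id -> label map
.assembleLabels <- function(cond, masks, condIdx) {
    px <- cond$pattern@pixelSizeUm
    nrF <- round(cond$pattern@fieldUm[1] / px)
    ncF <- round(cond$pattern@fieldUm[2] / px)
    lab <- matrix(0L, nrF, ncF)
    ids <- which(vapply(masks, function(m)
        !is.null(m) && m$cond == condIdx, logical(1)))
    map <- data.frame(platelet_id = integer(0), label = integer(0))
    lev <- 0L
    for (g in ids) {
        m <- masks[[g]]
        if (!length(m$idx)) next
        lev <- lev + 1L
        i <- (m$idx - 1L) %% m$nr + m$rows[1]
        j <- (m$idx - 1L) %/% m$nr + m$cols[1]
        lab[cbind(i, j)] <- lev
        map <- rbind(map, data.frame(platelet_id = g, label = lev))
    }
    list(lab = lab, map = map)
}

.writeDataset <- function(ds, outDir, nparams) {
    utils::write.csv(ds$groundTruth,
                     file.path(outDir, "ground_truth.csv"), row.names = FALSE)
    utils::write.csv(ds$filopodia,
                     file.path(outDir, "filopodia.csv"), row.names = FALSE)
    for (ci in seq_along(ds$conditions)) {
        cond <- ds$conditions[[ci]]
        tag <- sprintf("cond%02d_%s%g", ci, ds$config$series, cond$value)
        writePatternConfig(cond$pattern,
                           file.path(outDir, paste0(tag, "_pattern.yaml")))
        if (length(ds$images) >= ci && !is.null(ds$images[[ci]])) {
            img <- ds$images[[ci]]
            dn <- 2^nparams@bitDepth - 1
            for (ch in channelNames(img)) {
                tiff::writeTIFF(getChannel(img, ch) / dn,
                    file.path(outDir, paste0(tag, "_", ch, ".tif")),
                    bits.per.sample = nparams@bitDepth)
            }
        }
    }
    man <- ds$manifest
    man$files <- list.files(outDir)
    csvs <- file.path(outDir, c("ground_truth.csv", "filopodia.csv"))
    man$checksums <- as.list(tools::md5sum(csvs[file.exists(csvs)]))
    jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(outDir)
}

#' Measure simulated platelets from their ground-truth masks
#'
#' Runs the per-platelet metrics ([onPatternFraction()], [aspectRatio()],
#' [detectSpanning()], optionally [measureFilopodia()]) directly on the
#' noiseless simulator masks of a [generateDataset()] result -- the
#' measurement path that bypasses rendering and segmentation.
#'
#' @param ds result of \code{generateDataset(..., keepMasks = TRUE)}.
#' @param filopodia also run the skeleton-based filopodia measurement
#'   (slower).
#' @param bodyOpenUm,pruneUm see [measureFilopodia()].
#' @return list with \code{measurements} (one row per spread platelet) and
#'   \code{filopodiaLengths} (data.frame platelet_id, length_um) when
#'   requested.
#' @export
measureDataset <- function(ds, filopodia = FALSE, bodyOpenUm = 0.8,
                           pruneUm = 0.5) {
    if (!length(ds$masks))
        stop("dataset has no stored masks; rerun with keepMasks = TRUE")
    out <- list(); fl <- list()
    for (g in seq_along(ds$masks)) {
        m <- ds$masks[[g]]
        if (is.null(m)) next
        gtRow <- ds$groundTruth[ds$groundTruth$platelet_id == g, ]
        cond <- ds$conditions[[m$cond]]
        px <- cond$pattern@pixelSizeUm
        mask <- matrix(FALSE, m$nr, m$nc)
        mask[m$idx] <- TRUE
        if (!any(mask)) next
        win <- .rasterizeWindow(cond$pattern,
                                rows = m$rows + c(0L, 0L),
                                cols = m$cols + c(0L, 0L))
        regions <- list(axisAngle = cond$pattern@axisAngle,
                        stripes = cond$pattern@stripes,
                        gaps_um = stripeSeparations(cond$pattern),
                        idMap = win$idMap, pixelSizeUm = px)
        frac <- onPatternFraction(mask, win$mask)
        ar <- aspectRatio(mask, cond$pattern@axisAngle, px)
        sp <- detectSpanning(mask, regions)
        row <- data.frame(platelet_id = g,
                          condition_key = gtRow$condition_key,
                          condition_value = gtRow$condition_value,
                          area_um2 = sum(mask) * px^2,
                          on_pattern_fraction = frac,
                          length_along_um = ar["length_along_um"],
                          width_perp_um = ar["width_perp_um"],
                          aspect_ratio = ar["aspect_ratio"],
                          spans = sp$spans,
                          spanned_gap_um = sp$spanned_gap_um,
                          contacts_edge = sp$contacts_edge,
                          stripes_touched = paste(sp$stripes_touched,
                                                  collapse = ";"),
                          row.names = NULL)
        if (filopodia) {
            lens <- measureFilopodia(mask, px, bodyOpenUm = bodyOpenUm,
                                     pruneUm = pruneUm)
            row$n_filopodia_measured <- length(lens)
            row$filopodia_mean_um <-
                if (length(lens)) mean(lens) else NA_real_
            if (length(lens))
                fl[[length(fl) + 1L]] <- data.frame(platelet_id = g,
                                                    length_um = lens)
        }
        out[[length(out) + 1L]] <- row
    }
    res <- list(measurements = do.call(rbind, out))
    if (filopodia)
        res$filopodiaLengths <- if (length(fl)) do.call(rbind, fl) else
            data.frame(platelet_id = integer(0), length_um = numeric(0))
    res
}
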