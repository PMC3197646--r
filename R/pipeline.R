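#' Run the full micropattern-spreading pipeline
#'
#' Orchestrates the stages \code{simulate} (synthetic dataset + rendering),
#' \code{segment} (pattern + platelet masks from the rendered channels),
#' \code{measure} (per-platelet metrics) and \code{curves} (per-geometry
#' aggregation, exponential fits, plots) from one YAML configuration.
#' Outputs land under \code{outDir}: \code{data/} (images, ground truth),
#' \code{masks/}, \code{measurements.csv}, \code{curves.csv},
#' \code{fits.json}, \code{plots/} and a \code{manifest.json} recording the
#' config, seed, package version and output checksums. A rerun with the same
#' config and seed is byte-identical in the measurement tables.
#'
#' @param config path to a YAML run config, or an equivalent list. Fields:
#'   the [generateDataset()] experiment fields, plus optional
#'   \code{segmentation} ([SegmentationParams()] overrides), \code{fit_model}
#'   (see [fitExponential()]), \code{band_um}, \code{measure_filopodia}.
#' @param rngSeed integer seed for every stochastic stage.
#' @param outDir output directory.
#' @param stages subset of \code{c("simulate","segment","measure","curves")};
#'   "all" runs everything.
#' @param force overwrite an existing non-empty \code{outDir}.
#' @param logLevel "info" or "quiet".
#' @return invisibly, a list with the stage outputs (dataset, labels,
#'   measurements, curves, manifest path).
#' @export
runPipeline <- function(config, rngSeed, outDir, stages = "all",
                        force = FALSE, logLevel = c("info", "quiet")) {
    logLevel <- match.arg(logLevel)
    say <- function(...) if (logLevel == "info") message("[pipeline] ", ...)
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (identical(stages, "all"))
        stages <- c("simulate", "segment", "measure", "curves")
    if (missing(rngSeed) || is.null(rngSeed))
        stop("an explicit rngSeed is required")
    if (dir.exists(outDir) && length(list.files(outDir)) && !force)
        stop("output directory exists and is not empty; use force = TRUE")
    dir.create(file.path(outDir, "plots"), recursive = TRUE,
               showWarnings = FALSE)

    config$render <- TRUE
    segParams <- .overrideParams(SegmentationParams(), config$segmentation)
    fitModel <- config$fit_model
    bandUm <- config$band_um %||% 0.5
    res <- list()

    say("simulate: generating dataset")
    ds <- generateDataset(config, rngSeed,
                          outDir = file.path(outDir, "data"),
                          keepMasks = TRUE, force = force)
    res$dataset <- ds
    say(sprintf("simulate: %d platelets over %d conditions",
                nrow(ds$groundTruth), length(ds$conditions)))

    if (any(c("segment", "measure", "curves") %in% stages)) {
        say("segment: thresholding and labelling")
        dir.create(file.path(outDir, "masks"), showWarnings = FALSE)
        measurements <- list()
        for (ci in seq_along(ds$conditions)) {
            img <- ds$images[[ci]]
            patMask <- segmentPattern(img, segParams)
            labels <- segmentPlatelets(img, segParams)
            regions <- detectStripes(patMask, pixelSize(img))
            tag <- sprintf("cond%02d", ci)
            writeMaskTiff(labels, file.path(outDir, "masks",
                                            paste0(tag, "_labels.tif")))
            say(sprintf("segment: condition %g -> %d platelets",
                        ds$conditions[[ci]]$value, max(labels)))
            if (any(c("measure", "curves") %in% stages)) {
                actin <- if ("actin" %in% channelNames(img))
                    getChannel(img, "actin") else NULL
                mm <- measurePlatelets(labels, patMask, regions,
                    pixelSize(img), actinChannel = actin, bandUm = bandUm,
                    measureFilo = isTRUE(config$measure_filopodia))
                if (nrow(mm)) {
                    mm$condition_key <- ds$config$series
                    mm$condition_value <- ds$conditions[[ci]]$value
                    measurements[[ci]] <- mm
                }
            }
        }
        if (any(c("measure", "curves") %in% stages)) {
            meas <- do.call(rbind, measurements)
            utils::write.csv(meas, file.path(outDir, "measurements.csv"),
                             row.names = FALSE)
            res$measurements <- meas
            say(sprintf("measure: %d platelets measured, %d spanning",
                        nrow(meas), sum(meas$spans)))
        }
    }

    if ("curves" %in% stages && !is.null(res$measurements)) {
        say("curves: aggregating and fitting")
        gk <- ds$config$series
        stats <- if (gk == "width") c("on_pattern_fraction", "aspect_ratio")
                 else "spans"
        curves <- list(); fits <- list(); rows <- list()
        for (st in stats) {
            cu <- aggregateByGroup(res$measurements, groupKey = gk,
                                   statistic = st)
            model <- fitModel %||% switch(st,
                on_pattern_fraction = "rise_to_one",
                aspect_ratio = "decay_to_one",
                spans = "decay_to_zero")
            if (length(cu@x) >= 3) {
                cu <- fitExponential(cu, model)
                fits[[st]] <- c(list(model = cu@model),
                                as.list(cu@fitParams), cu@fitInfo)
            } else {
                say("curves: <3 groups for ", st, "; aggregation only")
                fits[[st]] <- list(model = NULL,
                                   message = "too few groups to fit")
            }
            curves[[st]] <- cu
            cd <- curveData(cu); cd$statistic <- st
            rows[[st]] <- cd
            grDevices::png(file.path(outDir, "plots",
                                     paste0(st, "_vs_", gk, ".png")),
                           width = 700, height = 500)
            plotGeometryCurve(cu, showMax = (st == "aspect_ratio"))
            grDevices::dev.off()
        }
        utils::write.csv(do.call(rbind, rows),
                         file.path(outDir, "curves.csv"), row.names = FALSE)
        jsonlite::write_json(fits, file.path(outDir, "fits.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        res$curves <- curves
    }

    files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
    csvs <- files[grepl("\\.csv$", files)]
    manifest <- list(config = config, rngSeed = rngSeed,
                     package_version = as.character(
                         utils::packageVersion("plateletPattern")),
                     stages = stages,
                     checksums = as.list(tools::md5sum(csvs)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$manifest <- file.path(outDir, "manifest.json")
    say("done")
    invisible(res)
}

#' Measure externally supplied images (no simulation)
#'
#' Stage-decoupled measurement: read a pattern channel and a membrane
#' channel from TIFF files, segment both, and produce the per-platelet
#' measurement table.
#'
#' @param patternTiff,membraneTiff single-channel TIFF paths.
#' @param pixelSizeUm um per pixel of the images.
#' @param params a [SegmentationParams-class].
#' @param actinTiff optional actin channel path.
#' @param bandUm edge band (um) for the actin ratio.
#' @return data.frame of per-platelet measurements.
#' @export
measureImages <- function(patternTiff, membraneTiff, pixelSizeUm,
                          params = SegmentationParams(), actinTiff = NULL,
                          bandUm = 0.5) {
    chans <- list(pattern = readImageTiff(patternTiff),
                  membrane = readImageTiff(membraneTiff))
    if (!is.null(actinTiff)) chans$actin <- readImageTiff(actinTiff)
    img <- LabeledImage(chans, pixelSizeUm,
                        provenance = list(pattern = patternTiff,
                                          membrane = membraneTiff))
    patMask <- segmentPattern(img, params)
    labels <- segmentPlatelets(img, params)
    regions <- detectStripes(patMask, pixelSizeUm)
    measurePlatelets(labels, patMask, regions, pixelSizeUm,
                     actinChannel = chans$actin, bandUm = bandUm)
}
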