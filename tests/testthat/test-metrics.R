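test_that("on-pattern fraction equals the brute-force pixel count oracle", {
    set.seed(101)
    for (rep in 1:100) {
        n <- sample(5:15, 1)
        plat <- matrix(runif(n * n) < 0.5, n, n)
        if (!any(plat)) plat[1, 1] <- TRUE
        pat <- matrix(runif(n * n) < 0.5, n, n)
        # brute-force double loop
        num <- 0L; den <- 0L
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (plat[i, j]) {
                den <- den + 1L
                if (pat[i, j]) num <- num + 1L
            }
        }
        expect_identical(onPatternFraction(plat, pat), num / den)
    }
})

test_that("on-pattern fraction hits its boundary cases", {
    pat <- matrix(FALSE, 20, 20); pat[, 1:10] <- TRUE
    inside <- matrix(FALSE, 20, 20); inside[5:10, 2:8] <- TRUE
    outside <- matrix(FALSE, 20, 20); outside[5:10, 12:18] <- TRUE
    expect_equal(onPatternFraction(inside, pat), 1.0)
    expect_equal(onPatternFraction(outside, pat), 0.0)
    expect_error(onPatternFraction(matrix(FALSE, 20, 20), pat), "empty")
    expect_error(onPatternFraction(inside, matrix(TRUE, 5, 5)), "shape")
})

test_that("aspect ratio reproduces the constrained-rectangle and disc limits", {
    # 11.4 um x 0.6 um rectangle on a 0.6 um stripe: ratio 19.0
    ar <- aspectRatio(rectMask(11.4, 0.6), 0, 0.1)
    expect_equal(ar[["aspect_ratio"]], 19.0)
    expect_equal(ar[["length_along_um"]], 11.4)
    expect_equal(ar[["width_perp_um"]], 0.6)
    # isotropic disc: exactly 1 regardless of diameter
    expect_identical(aspectRatio(discMask(5), 0, 0.1)[["aspect_ratio"]], 1)
    expect_identical(aspectRatio(discMask(12.8), 0, 0.1)[["aspect_ratio"]], 1)
    expect_error(aspectRatio(matrix(FALSE, 5, 5), 0, 0.1), "empty")
})

test_that("aspect ratio is equivariant under joint rotation of mask and axis", {
    # extents follow the pixel-centre hull plus one pixel, so equivariance
    # holds to 5% once the narrow side is well resolved (>= ~20 px)
    ar0 <- aspectRatio(rotatedRectMask(11.4, 2, 0), 0, 0.1)
    for (ang in c(17, 37, 90, 146)) {
        arA <- aspectRatio(rotatedRectMask(11.4, 2, ang), ang, 0.1)
        expect_equal(arA[["aspect_ratio"]], ar0[["aspect_ratio"]],
                     tolerance = 0.05)
    }
    # the 19:1 constrained-platelet rectangle at a finer pixel scale
    px <- 0.025
    ref <- aspectRatio(rotatedRectMask(11.4, 0.6, 0, px = px, fieldUm = 15),
                       0, px)
    rot <- aspectRatio(rotatedRectMask(11.4, 0.6, 37, px = px, fieldUm = 15),
                       37, px)
    expect_equal(rot[["aspect_ratio"]], ref[["aspect_ratio"]],
                 tolerance = 0.05)
})

test_that("aspect ratio grows monotonically under axis-aligned elongation", {
    m <- rectMask(3, 1)
    base <- aspectRatio(m, 0, 0.1)[["aspect_ratio"]]
    prev <- base
    for (extra in c(5, 10, 20)) {
        m2 <- rectMask(3 + extra * 0.1, 1)
        cur <- aspectRatio(m2, 0, 0.1)[["aspect_ratio"]]
        expect_gte(cur, prev)
        prev <- cur
    }
    # a platelet wider than long has ratio < 1 (not clamped)
    expect_lt(aspectRatio(rectMask(1, 4), 0, 0.1)[["aspect_ratio"]], 1)
})

test_that("spanning classification distinguishes interior, edge and bridging platelets", {
    p <- makeSeparationSeries(8, 3, fieldUm = c(40, 40), originOffsetUm = 8)
    reg <- stripeRegions(p)
    n <- nrow(reg$idMap)
    mk <- function(rowsUm, colsUm = c(5, 15)) {
        m <- matrix(FALSE, n, n)
        m[round(rowsUm[1] / 0.1):round(rowsUm[2] / 0.1),
          round(colsUm[1] / 0.1):round(colsUm[2] / 0.1)] <- TRUE
        m
    }
    # stripe 1 spans rows 8..16 um, gap 16..19, stripe 2 19..27
    bridging <- mk(c(12, 22))
    r <- detectSpanning(bridging, reg)
    expect_true(r$spans)
    expect_equal(r$stripes_touched, c(1, 2))
    expect_equal(r$spanned_gap_um, 3)
    expect_true(r$contacts_edge)

    interior <- mk(c(10, 14))
    r2 <- detectSpanning(interior, reg)
    expect_false(r2$spans)
    expect_false(r2$contacts_edge)
    expect_true(is.na(r2$spanned_gap_um))

    edgeOnly <- mk(c(10, 16.05))   # reaches the last stripe-1 pixel row
    r3 <- detectSpanning(edgeOnly, reg)
    expect_false(r3$spans)
    expect_true(r3$contacts_edge)

    expect_error(detectSpanning(interior, list(idMap = NULL,
        stripes = data.frame())), "no stripes")
})

test_that("spanning flags from masks agree with the simulator ground truth", {
    cfg <- list(series = "separation", separations_um = c(2, 4, 6),
                width_um = 10, n_per_condition = 40,
                seed_placement = "edge_adjacent")
    ds <- generateDataset(cfg, rngSeed = 13)
    md <- measureDataset(ds)
    m <- md$measurements
    gt <- ds$groundTruth[match(m$platelet_id, ds$groundTruth$platelet_id), ]
    expect_gte(mean(m$spans == gt$spans), 0.99)
})

test_that("filopodium length is recovered from a synthetic spike", {
    m <- spikedDisc(diameterUm = 5, spikeUm = 3)
    lens <- measureFilopodia(m, 0.1)
    expect_length(lens, 1)
    expect_equal(lens, 3.0, tolerance = 0.2 / 3)
    # a plain disc has no protrusions
    expect_length(measureFilopodia(discMask(5), 0.1), 0)
    expect_error(measureFilopodia(matrix(FALSE, 5, 5), 0.1), "empty")
    # pruning removes sub-threshold stubs
    stub <- spikedDisc(5, 0.3)
    expect_length(measureFilopodia(stub, 0.1, pruneUm = 0.5), 0)
})

test_that("pooled filopodia measurement recovers the generator mean", {
    cfg <- list(series = "width", widths_um = 10, n_per_condition = 60)
    ds <- generateDataset(cfg, rngSeed = 21)
    md <- measureDataset(ds, filopodia = TRUE)
    L <- md$filopodiaLengths$length_um
    expect_gt(length(L), 100)
    expect_equal(mean(L), 3.10, tolerance = 0.25 / 3.10)
})

test_that("edge enrichment reads back the rendered factor and is 1 for homogeneous channels", {
    cfg <- list(series = "width", widths_um = 8, n_per_condition = 4,
                render = TRUE, actin_edge_factor = 3)
    ds <- generateDataset(cfg, rngSeed = 31)
    img <- ds$images[[1]]
    pat <- segmentPattern(img)
    labs <- segmentPlatelets(img)
    actin <- getChannel(img, "actin")
    tub <- getChannel(img, "tubulin")
    ratios <- tubRatios <- numeric(0)
    for (k in seq_len(max(labs))) {
        mk <- labs == k
        ratios <- c(ratios, edgeIntensityRatio(actin, mk, pat, 0.1))
        tubRatios <- c(tubRatios, edgeIntensityRatio(tub, mk, pat, 0.1))
    }
    expect_equal(mean(ratios), 3, tolerance = 0.2)
    expect_equal(mean(tubRatios), 1, tolerance = 0.1)
})

test_that("edge enrichment rejects degenerate geometry", {
    pat <- matrix(TRUE, 20, 20)
    tiny <- matrix(FALSE, 20, 20); tiny[10, 10] <- TRUE
    ch <- matrix(1, 20, 20)
    expect_error(edgeIntensityRatio(ch, tiny, pat, 0.1, bandUm = 5),
                 "undefined measurement")
    expect_error(edgeIntensityRatio(ch, tiny, pat, 0.1, bandUm = 0), "bandUm")
    # zero-intensity interior
    p2 <- matrix(FALSE, 40, 40); p2[10:30, 10:30] <- TRUE
    pat2 <- matrix(FALSE, 40, 40); pat2[, 1:20] <- TRUE
    expect_error(edgeIntensityRatio(matrix(0, 40, 40), p2, pat2, 0.1),
                 "zero-intensity")
})

test_that("simulated platelets on wide stripes are conformal and near-isotropic", {
    cfg <- list(series = "width", widths_um = c(6, 10, 20),
                n_per_condition = 30)
    ds <- generateDataset(cfg, rngSeed = 17)
    m <- measureDataset(ds)$measurements
    byW <- split(m, m$condition_value)
    for (w in names(byW))
        expect_gte(mean(byW[[w]]$on_pattern_fraction), 0.95)
    means <- vapply(byW, function(d) mean(d$aspect_ratio), numeric(1))
    # aspect ratio approaches 1 from above as width grows
    expect_true(all(diff(means[order(as.numeric(names(means)))]) < 0))
    expect_gt(means[["20"]], 0.8)
    expect_lt(means[["20"]], 1.3)
})
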