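widePattern <- function() makeWidthSeries(10, 0, fieldUm = c(30, 30),
                                          originOffsetUm = 10)

test_that("a platelet seeded on a wide stripe conforms fully to the protein", {
    p <- widePattern()
    s <- simulatePlatelet(p, c(15, 15), SpreadingParams(), rngSeed = 1)
    expect_true(s$groundTruth$spread)
    expect_equal(s$groundTruth$on_pattern_fraction, 1.0)
    expect_false(s$groundTruth$spans)
    expect_gt(s$groundTruth$area_um2, 45)
})

test_that("a platelet out of filopodial reach of any protein never spreads", {
    # seed 8 um from the stripe edge: beyond bodyRadius + maxReach
    p <- makeWidthSeries(10, 0, fieldUm = c(40, 40), originOffsetUm = 28)
    s <- simulatePlatelet(p, c(20, 20), SpreadingParams(), rngSeed = 42)
    expect_false(s$groundTruth$spread)
    expect_false(any(s$mask))
    expect_false(any(s$filopodia$anchored))
})

test_that("simulation contract: explicit seed required, seed must be in field", {
    p <- widePattern()
    expect_error(simulatePlatelet(p, c(15, 15), SpreadingParams()),
                 "rngSeed")
    expect_error(simulatePlatelet(p, c(99, 15), SpreadingParams(),
                                  rngSeed = 1), "outside the")
    expect_identical(
        simulatePlatelet(p, c(15, 15), SpreadingParams(), rngSeed = 9),
        simulatePlatelet(p, c(15, 15), SpreadingParams(), rngSeed = 9))
})

test_that("filopodia lengths are truncated at max reach and match the target distribution", {
    cfg <- list(series = "width", widths_um = 10, n_per_condition = 60)
    ds <- generateDataset(cfg, rngSeed = 2, keepMasks = FALSE)
    len <- ds$filopodia$length_um
    expect_true(all(len > 0 & len <= 5))
    # drawn lengths approach the generator mean within 2 SD/sqrt(n)
    expect_lt(abs(mean(len) - 3.10), 2 * 0.8 / sqrt(length(len)) + 0.02)
})

test_that("no simulated platelet ever spans a gap wider than max reach", {
    cfg <- list(series = "separation", separations_um = c(3, 5.5, 7),
                width_um = 10, n_per_condition = 50,
                seed_placement = "edge_adjacent")
    ds <- generateDataset(cfg, rngSeed = 5, keepMasks = FALSE)
    gt <- ds$groundTruth
    sp <- gt[gt$spans, ]
    expect_true(all(sp$spanned_gap_um <= 5))
    expect_true(all(sp$condition_value <= 5))
    # some spanning at 3 um, none at 7 um
    expect_gt(sum(gt$spans[gt$condition_value == 3]), 0)
    expect_equal(sum(gt$spans[gt$condition_value == 7]), 0)
})

test_that("with full conformity every mask pixel off-pattern lies in a gap corridor", {
    # non-spanning platelets: exact set inclusion in the pattern
    cfg <- list(series = "width", widths_um = c(6, 10), n_per_condition = 15)
    ds <- generateDataset(cfg, rngSeed = 8)
    for (g in seq_along(ds$masks)) {
        m <- ds$masks[[g]]
        gt <- ds$groundTruth[ds$groundTruth$platelet_id == g, ]
        if (!length(m$idx) || gt$spans) next
        win <- plateletPattern:::.rasterizeWindow(
            ds$conditions[[m$cond]]$pattern, m$rows, m$cols)
        mask <- matrix(FALSE, m$nr, m$nc); mask[m$idx] <- TRUE
        expect_true(all(win$mask[mask]))
    }
})

test_that("thin-stripe fidelity loss admits off-pattern pixels only when enabled", {
    p <- makeWidthSeries(2, 0, fieldUm = c(30, 30), originOffsetUm = 14)
    conform <- SpreadingParams()
    leaky <- SpreadingParams(offPatternSpread = TRUE, conformFidelity = 0.5)
    s1 <- simulatePlatelet(p, c(15, 15), conform, rngSeed = 3)
    s2 <- simulatePlatelet(p, c(15, 15), leaky, rngSeed = 3)
    expect_equal(s1$groundTruth$on_pattern_fraction, 1.0)
    expect_lt(s2$groundTruth$on_pattern_fraction, 1.0)
    expect_gt(s2$groundTruth$on_pattern_fraction, 0.3)
})

test_that("ground-truth mean on-pattern fraction rises with stripe width", {
    cfg <- list(series = "width", widths_um = c(1, 3, 10),
                n_per_condition = 25,
                spreading = list(offPatternSpread = TRUE,
                                 conformFidelity = 0.6))
    ds <- generateDataset(cfg, rngSeed = 4, keepMasks = FALSE)
    m <- aggregate(on_pattern_fraction ~ condition_value,
                   ds$groundTruth, mean)
    expect_true(all(diff(m$on_pattern_fraction) > 0))
    expect_gt(m$on_pattern_fraction[3], 0.98)
})

test_that("dataset generation is deterministic and order-independent in its seed", {
    cfg <- list(series = "width", widths_um = c(5, 10), n_per_condition = 6)
    d1 <- generateDataset(cfg, rngSeed = 77, keepMasks = FALSE)
    d2 <- generateDataset(cfg, rngSeed = 77, keepMasks = FALSE)
    expect_identical(d1$groundTruth, d2$groundTruth)
    expect_identical(d1$filopodia, d2$filopodia)
    d3 <- generateDataset(cfg, rngSeed = 78, keepMasks = FALSE)
    expect_false(identical(d1$groundTruth, d3$groundTruth))
})

test_that("zero platelets gives empty-but-valid outputs with a warning", {
    cfg <- list(series = "width", widths_um = 5, n_per_condition = 0)
    expect_warning(ds <- generateDataset(cfg, rngSeed = 1), "zero platelets")
    expect_equal(nrow(ds$groundTruth), 0)
})

test_that("renderer is exact without noise and deterministic with it", {
    p <- makeWidthSeries(c(2, 3), 4, 0, fieldUm = c(20, 20),
                         originOffsetUm = 3)
    pm <- rasterizePattern(p)
    lab <- matrix(0L, nrow(pm), ncol(pm)); lab[80:120, 80:120] <- 1L
    img <- renderImage(pm, lab, noiselessNoise(), c("pattern", "membrane"),
                       rngSeed = 1)
    expect_true(all(getChannel(img, "membrane") == (lab > 0) * 65535))
    expect_true(all(getChannel(img, "pattern") == pm * 65535))

    a <- renderImage(pm, lab, NoiseParams(), c("membrane", "actin"),
                     rngSeed = 5)
    b <- renderImage(pm, lab, NoiseParams(), c("membrane", "actin"),
                     rngSeed = 5)
    expect_identical(a@channels, b@channels)

    expect_error(renderImage(pm, NULL, NoiseParams(), c("membrane"),
                             rngSeed = 1), "without a platelet label")
    expect_error(renderImage(pm, lab, NoiseParams(), c("dapi"),
                             rngSeed = 1), "unknown channel")
})

test_that("rendered actin is elevated by the edge factor inside the boundary band", {
    p <- makeWidthSeries(6, 0, fieldUm = c(20, 20), originOffsetUm = 7)
    pm <- rasterizePattern(p)
    # platelet filling the stripe locally: its edge bands coincide with the
    # pattern boundary on two sides
    lab <- matrix(0L, nrow(pm), ncol(pm))
    lab[, 60:140] <- pm[, 60:140] * 1L
    img <- renderImage(pm, lab, noiselessNoise(), "actin",
                       actinEdgeFactor = 3, bandUm = 0.3, rngSeed = 1)
    r <- edgeIntensityRatio(getChannel(img, "actin"), lab > 0, pm,
                            0.1, bandUm = 0.3)
    expect_equal(r, 3, tolerance = 1e-6)
})
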