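test_that("width series places stripes at cumulative offsets with constant separation", {
    p <- makeWidthSeries(c(1, 2, 4), separationUm = 3, fieldUm = c(30, 30))
    expect_equal(stripeTable(p)$offset_um, c(0, 4, 9))
    expect_equal(stripeTable(p)$width_um, c(1, 2, 4))
    expect_equal(stripeSeparations(p), c(3, 3))

    widths <- c(0.5, 1, 2, 5, 10, 20)
    p2 <- makeWidthSeries(widths, 10, fieldUm = c(100, 100))
    expect_equal(stripeSeparations(p2), rep(10, length(widths) - 1))

    p3 <- makeWidthSeries(5, 0, fieldUm = c(20, 20))
    expect_equal(nrow(stripeTable(p3)), 1)
})

test_that("separation series realizes the requested gaps", {
    p <- makeSeparationSeries(2, c(5, 5), fieldUm = c(30, 30))
    expect_equal(stripeTable(p)$offset_um, c(0, 7, 14))
    seps <- c(0.5, 1, 2, 4, 8, 20)
    p2 <- makeSeparationSeries(10, seps, fieldUm = c(120, 120))
    expect_equal(stripeSeparations(p2), seps)
    expect_equal(nrow(stripeTable(makeSeparationSeries(10, numeric(0)))), 1)
})

test_that("construction rejects invalid geometry with informative sizing errors", {
    expect_error(makeWidthSeries(c(1, -2), 3), "width")
    expect_error(makeWidthSeries(c(10, 10), 10, fieldUm = c(20, 20)),
                 "field too small")
    expect_error(makeSeparationSeries(10, c(-1)), "separation")
})

test_that("rasterization follows the pixel-centre rule exactly", {
    p <- makeWidthSeries(0.6, 0, fieldUm = c(5, 5), pixelSizeUm = 0.1,
                         originOffsetUm = 2)
    m <- rasterizePattern(p)
    expect_equal(sum(rowSums(m) > 0), 6)       # 0.6 um at 0.1 um/px = 6 px
    expect_equal(sum(m), 6 * ncol(m))

    empty <- new("StripePattern", axisAngle = 0,
                 stripes = data.frame(offset_um = numeric(0),
                                      width_um = numeric(0)),
                 fieldUm = c(5, 5), pixelSizeUm = 0.1)
    expect_false(any(rasterizePattern(empty)))

    # idempotence and 0/90-degree transpose symmetry
    expect_identical(m, rasterizePattern(p))
    p0 <- makeWidthSeries(c(2, 3), 4, 0, fieldUm = c(20, 20),
                          originOffsetUm = 3)
    p90 <- makeWidthSeries(c(2, 3), 4, 90, fieldUm = c(20, 20),
                           originOffsetUm = 3)
    expect_identical(rasterizePattern(p90), t(rasterizePattern(p0)))
})

test_that("on-pattern pixel count equals the sum over disjoint stripes", {
    p <- makeWidthSeries(c(1, 2, 4), 3, fieldUm = c(30, 30),
                         originOffsetUm = 5)
    id <- stripeIdMap(p)
    perStripe <- tabulate(id[id > 0], nbins = 3)
    expect_equal(sum(rasterizePattern(p)), sum(perStripe))
    # widths in pixels times field width
    expect_equal(perStripe, round(c(1, 2, 4) / 0.1) * ncol(id))
})

test_that("rasterize -> detect round trip recovers geometry within a pixel", {
    p <- makeWidthSeries(c(2, 4, 8), 6, fieldUm = c(50, 50),
                         originOffsetUm = 8)
    r <- detectStripes(rasterizePattern(p), pixelSize(p))
    expect_equal(r$stripes$width_um, c(2, 4, 8), tolerance = 0.1 / 2)
    expect_equal(r$gaps_um, c(6, 6), tolerance = 0.11)
    expect_lt(abs(r$axisAngle %% 180 - 0) %% 180, 1)

    # rotated pattern: axis recovered within a degree
    p30 <- makeWidthSeries(c(4, 4), 6, axisAngle = 30, fieldUm = c(60, 60),
                           originOffsetUm = 15)
    r30 <- detectStripes(rasterizePattern(p30), 0.1)
    expect_lt(abs(r30$axisAngle - 30), 1)
    expect_equal(r30$stripes$width_um, c(4, 4), tolerance = 0.1)

    # single full-field rectangle: one stripe, no gaps
    one <- detectStripes(matrix(TRUE, 40, 40), 0.1)
    expect_equal(nrow(one$stripes), 1)
    expect_length(one$gaps_um, 0)

    expect_error(detectStripes(matrix(FALSE, 10, 10), 0.1), "no pattern")
})

test_that("pattern configs round-trip through YAML", {
    p <- makeWidthSeries(c(1.5, 3), 2.5, axisAngle = 15,
                         fieldUm = c(25, 40), originOffsetUm = 4)
    f <- withr::local_tempfile(fileext = ".yaml")
    writePatternConfig(p, f)
    q <- readPatternConfig(f)
    expect_equal(stripeTable(q), stripeTable(p))
    expect_equal(axisAngle(q), 15)
    expect_equal(fieldDim(q), c(25, 40))
})
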