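handTable <- function() {
    # two groups, hand-computable means and SEMs
    data.frame(
        condition_value = c(2, 2, 2, 8, 8, 8),
        on_pattern_fraction = c(0.2, 0.4, 0.6, 0.9, 1.0, 0.8),
        aspect_ratio = c(3, 5, 7, 1, 2, 3),
        spans = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
        contacts_edge = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
}

test_that("group means, SEMs, n and maxima match hand arithmetic", {
    cu <- aggregateByGroup(handTable(), "width", "on_pattern_fraction")
    cd <- curveData(cu)
    expect_equal(cd$x, c(2, 8))
    expect_equal(cd$mean, c(0.4, 0.9))
    expect_equal(cd$sem, c(sd(c(0.2, 0.4, 0.6)) / sqrt(3),
                           sd(c(0.9, 1.0, 0.8)) / sqrt(3)))
    expect_equal(cd$n, c(3L, 3L))
    expect_equal(cd$max_observed, c(0.6, 1.0))
})

test_that("spanning aggregates as an edge-contact proportion with binomial SEM", {
    cu <- aggregateByGroup(handTable(), "separation", "spans")
    cd <- curveData(cu)
    # group 2: 2/3 span; group 8: only 2 edge-contacting platelets, 0 span
    expect_equal(cd$mean, c(2 / 3, 0))
    expect_equal(cd$n, c(3L, 2L))
    expect_equal(cd$sem[1], sqrt((2 / 3) * (1 / 3) / 3))
    expect_equal(cd$sem[2], 0)
})

test_that("aggregation flags singletons, rejects empties, ignores row order", {
    df <- handTable()
    one <- df[c(1, 4:6), ]
    cu <- aggregateByGroup(one, "width", "on_pattern_fraction")
    expect_equal(cu@fitInfo$singleton_groups, 2)
    expect_equal(curveData(cu)$sem[1], 0)
    expect_error(aggregateByGroup(df[0, ], "width", "on_pattern_fraction"),
                 "empty")
    shuffled <- df[sample(nrow(df)), ]
    expect_equal(aggregateByGroup(shuffled, "width", "aspect_ratio"),
                 aggregateByGroup(df, "width", "aspect_ratio"))
    # constant measurements have SEM 0
    cst <- data.frame(condition_value = c(1, 1, 1),
                      on_pattern_fraction = c(0.5, 0.5, 0.5))
    expect_equal(curveData(aggregateByGroup(cst, "width",
        "on_pattern_fraction"))$sem, 0)
})

test_that("each exponential model recovers its own exact parameters", {
    x <- c(0.5, 1, 2, 3, 4, 6, 8, 10, 15, 20)
    mk <- function(y, st) new("GeometryCurve", x = x, mean = y,
        sem = rep(0, length(x)), n = rep(5L, length(x)), maxObserved = y,
        statistic = st, groupKey = "width")

    f1 <- fitExponential(mk(1 - 0.8 * exp(-x / 2), "on_pattern_fraction"),
                         "rise_to_one")
    expect_equal(unname(fitParams(f1)), c(0.8, 2), tolerance = 1e-6)
    expect_true(f1@fitInfo$converged)

    f2 <- fitExponential(mk(1 + 6 * exp(-x / 1.5), "aspect_ratio"),
                         "decay_to_one")
    expect_equal(unname(fitParams(f2)), c(6, 1.5), tolerance = 1e-6)

    f3 <- fitExponential(mk(0.9 * exp(-x / 2.5), "spans"), "decay_to_zero")
    expect_equal(unname(fitParams(f3)), c(0.9, 2.5), tolerance = 1e-6)

    two <- new("GeometryCurve", x = x[1:2], mean = c(0.5, 0.4),
               sem = c(0, 0), n = c(3L, 3L), maxObserved = c(0.5, 0.4),
               statistic = "spans", groupKey = "separation")
    expect_error(fitExponential(two, "decay_to_zero"), "at least 3")
})

test_that("a constant curve at the asymptote is flagged degenerate, not fitted silently", {
    x <- c(1, 5, 10, 20)
    cu <- new("GeometryCurve", x = x, mean = rep(1, 4), sem = rep(0, 4),
              n = rep(4L, 4), maxObserved = rep(1, 4),
              statistic = "on_pattern_fraction", groupKey = "width")
    f <- fitExponential(cu, "rise_to_one")
    expect_true(f@fitInfo$degenerate)
    expect_equal(unname(fitParams(f)[["a"]]), 0)
    expect_true(is.na(fitParams(f)[["b"]]))
})

test_that("spanning threshold is the largest spanned gap, monotone under new events", {
    df <- data.frame(spans = c(TRUE, TRUE, TRUE, FALSE),
                     spanned_gap_um = c(1, 3, 4.5, NA))
    expect_equal(spanningThreshold(df), 4.5)
    more <- rbind(df, data.frame(spans = TRUE, spanned_gap_um = 4.8))
    expect_gte(spanningThreshold(more), spanningThreshold(df))
    none <- data.frame(spans = c(FALSE, FALSE),
                       spanned_gap_um = c(NA_real_, NA_real_))
    t0 <- spanningThreshold(none)
    expect_equal(as.numeric(t0), 0)
    expect_true(attr(t0, "no_spanning"))
})

test_that("fitted spanning curve predicts essentially no spanning past 5 um", {
    cfg <- list(series = "separation",
                separations_um = c(0.5, 1, 2, 3, 4, 5, 6, 8),
                width_um = 10, n_per_condition = 40,
                seed_placement = "edge_adjacent")
    ds <- generateDataset(cfg, rngSeed = 19)
    m <- measureDataset(ds)$measurements
    cu <- fitExponential(aggregateByGroup(m, "separation", "spans"),
                         "decay_to_zero")
    # no spanning is ever observed past 5 um, and the fitted decay is
    # negligible well beyond the filopodial reach
    expect_true(all(m$spans[m$condition_value > 5] == FALSE))
    expect_true(all(predictCurve(cu, c(8, 10, 20)) < 0.05))
    # monotone decrease of the spanning fraction with separation
    expect_lt(cor(curveData(cu)$x, curveData(cu)$mean, method = "spearman"),
              0)
})
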