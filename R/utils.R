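# Internal geometry and raster helpers.
#
# Conventions (documented in the methods vignette and config schema):
#   * matrices are (row, col) = (y, x), 1-based in R, pixel centres at
#     ((i - 0.5) * px, (j - 0.5) * px) in um from the field origin;
#   * the stripe axis angle is measured counterclockwise from +x when the
#     image is displayed with y up; axis unit vector u = (cos a, -sin a) in
#     (x, y_row) coordinates, perpendicular v = (sin a, cos a);
#   * a stripe occupies perpendicular coordinate p in [offset, offset+width).

.axisVectors <- function(angleDeg) {
    a <- angleDeg * pi / 180
    list(u = c(cos(a), -sin(a)), v = c(sin(a), cos(a)))
}

# perpendicular coordinate of points (x um, y um) w.r.t. an axis angle
.perpCoord <- function(x, y, angleDeg) {
    a <- angleDeg * pi / 180
    x * sin(a) + y * cos(a)
}

.alongCoord <- function(x, y, angleDeg) {
    a <- angleDeg * pi / 180
    x * cos(a) - y * sin(a)
}

# stripe index (0 = background) for perpendicular coordinates p, given the
# stripe table; half-open intervals [offset, offset + width)
.stripeIndexAt <- function(p, stripes) {
    idx <- integer(length(p))
    if (nrow(stripes) == 0) return(idx)
    for (k in seq_len(nrow(stripes))) {
        hit <- p >= stripes$offset_um[k] &
               p < stripes$offset_um[k] + stripes$width_um[k]
        idx[hit] <- k
    }
    idx
}

# perpendicular gap (um) between two stripes of a table (0 if adjacent ids
# overlap-adjacent); i < j not required
.stripeGap <- function(stripes, i, j) {
    if (i == j) return(0)
    a <- min(i, j); b <- max(i, j)
    stripes$offset_um[b] - (stripes$offset_um[a] + stripes$width_um[a])
}

# truncated-normal draw on (lo, hi] by rejection (narrow truncation is never
# extreme here: mean 3.1, sd 0.8, (0, 5])
.rtruncnorm <- function(n, mean, sd, lo = 0, hi = Inf) {
    out <- numeric(0)
    while (length(out) < n) {
        x <- stats::rnorm(n, mean, sd)
        out <- c(out, x[x > lo & x <= hi])
    }
    out[seq_len(n)]
}

# Deterministic per-unit seed splitting: one base seed drives every unit of
# work independently of execution order. Kept below 2^31.
.splitSeed <- function(base, unit, stream = 0L) {
    (as.double(base) %% 2147483647 * 1 + 1000003 * unit + 7919 * stream) %%
        2147483629 + 1
}

# run expr with a locally-seeded RNG, restoring the global RNG state
.withSeed <- function(seed, expr) {
    if (is.null(seed) || is.na(seed))
        stop("an explicit rngSeed is required (reproducibility contract)")
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed %% 2147483647))
    expr
}

# Connected-component labelling with selectable connectivity. EBImage's
# bwlabel is 4-connected only, so adjacency is built here (vectorized pixel
# shifts) and components come from igraph. Labels are 1..K in raster-scan
# order of each component's first pixel; background is 0.
.labelMask <- function(mask, connectivity = 8L) {
    stopifnot(connectivity %in% c(4L, 8L))
    nr <- nrow(mask); nc <- ncol(mask)
    fg <- which(mask)
    if (!length(fg)) return(matrix(0L, nr, nc))
    pos <- match(seq_len(nr * nc), fg)    # linear index -> vertex id
    row <- (fg - 1L) %% nr + 1L
    edges <- integer(0)
    addShift <- function(dr, dc) {
        nb <- fg + dr + dc * nr
        ok <- rep(TRUE, length(fg))
        if (dr == 1L) ok <- row < nr
        if (dr == -1L) ok <- row > 1L
        col <- (fg - 1L) %/% nr + 1L
        if (dc == 1L) ok <- ok & col < nc
        if (dc == -1L) ok <- ok & col > 1L
        nbv <- pos[nb[ok]]
        keep <- !is.na(nbv)
        rbind(which(ok)[keep], nbv[keep])
    }
    e <- cbind(addShift(1L, 0L), addShift(0L, 1L))
    if (connectivity == 8L)
        e <- cbind(e, addShift(1L, 1L), addShift(-1L, 1L))
    g <- igraph::graph_from_edgelist(t(e), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
    # relabel by first occurrence (raster order of fg, which is sorted)
    lev <- unique(memb)
    lab <- matrix(0L, nr, nc)
    lab[fg] <- match(memb, lev)
    lab
}

# Jaccard overlap of two logical masks
.jaccard <- function(a, b) {
    u <- sum(a | b)
    if (u == 0) return(1)
    sum(a & b) / u
}

# Rasterize the 1-px-wide segment p0 -> p1 (um coords) onto the window grid
# (originUm = um position of the window's (0,0) corner). Returns linear
# indices into an nr x nc matrix; dense point sampling at 0.3 px steps.
.rasterSegment <- function(p0, p1, px, nr, nc, originUm = c(0, 0)) {
    len <- sqrt(sum((p1 - p0)^2))
    n <- max(2L, ceiling(len / (0.3 * px)) + 1L)
    t <- seq(0, 1, length.out = n)
    x <- p0[1] + t * (p1[1] - p0[1])
    y <- p0[2] + t * (p1[2] - p0[2])
    j <- floor((x - originUm[1]) / px) + 1L
    i <- floor((y - originUm[2]) / px) + 1L
    ok <- i >= 1L & i <= nr & j >= 1L & j <= nc
    unique((j[ok] - 1L) * nr + i[ok])
}

# Geodesic lengths within a protrusion component: Dijkstra over the pixel
# grid with octile weights (1 orthogonal, sqrt(2) diagonal), started from the
# given seed pixels; returns the max finite distance (in px units).
.geodesicMax <- function(inset, seeds, nr, nc) {
    dist <- rep(Inf, length(inset))
    names(dist) <- as.character(inset)
    lookup <- seq_along(inset)
    names(lookup) <- as.character(inset)
    dist[as.character(seeds)] <- 0
    # simple Dijkstra on a small component
    visited <- rep(FALSE, length(inset))
    repeat {
        d <- dist; d[visited] <- Inf
        k <- which.min(d)
        if (!is.finite(d[k])) break
        visited[k] <- TRUE
        p <- inset[k]
        i <- (p - 1L) %% nr + 1L
        j <- (p - 1L) %/% nr + 1L
        for (dr in -1:1) for (dc in -1:1) {
            if (dr == 0 && dc == 0) next
            ii <- i + dr; jj <- j + dc
            if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
            q <- (jj - 1L) * nr + ii
            m <- lookup[as.character(q)]
            if (is.na(m) || visited[m]) next
            w <- if (dr != 0 && dc != 0) sqrt(2) else 1
            if (dist[k] + w < dist[m]) dist[m] <- dist[k] + w
        }
    }
    mx <- max(dist[is.finite(dist)])
    mx
}
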