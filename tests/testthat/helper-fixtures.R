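# Shared fixtures, built in code.

# solid axis-aligned rectangle mask: lengthUm along x, widthUm along y
rectMask <- function(lengthUm, widthUm, px = 0.1, pad = 20) {
    nl <- round(lengthUm / px); nw <- round(widthUm / px)
    m <- matrix(FALSE, nw + 2 * pad, nl + 2 * pad)
    m[pad + seq_len(nw), pad + seq_len(nl)] <- TRUE
    m
}

# solid disc mask of the given diameter, by the pixel-centre rule
discMask <- function(diameterUm, px = 0.1, pad = 10) {
    r <- diameterUm / 2
    n <- round(diameterUm / px) + 2 * pad
    c0 <- (n / 2) * px
    xy <- ((seq_len(n) - 0.5) * px) - c0
    d2 <- outer(xy^2, xy^2, `+`)
    d2 <= r^2
}

# rectangle rotated by angleDeg about its centre, rasterized analytically
rotatedRectMask <- function(lengthUm, widthUm, angleDeg, px = 0.1,
                            fieldUm = 30) {
    n <- round(fieldUm / px)
    c0 <- fieldUm / 2
    x <- (seq_len(n) - 0.5) * px - c0
    a <- angleDeg * pi / 180
    X <- matrix(x, n, n, byrow = TRUE)   # X[i, j] = x of column j
    Y <- matrix(x, n, n)                 # Y[i, j] = y of row i
    al <- X * cos(a) - Y * sin(a)
    pp <- X * sin(a) + Y * cos(a)
    abs(al) <= lengthUm / 2 & abs(pp) <= widthUm / 2
}

# disc with one straight 1-px spike of the given length from its edge
spikedDisc <- function(diameterUm = 5, spikeUm = 3, px = 0.1) {
    m <- discMask(diameterUm, px, pad = round(spikeUm / px) + 5)
    n <- nrow(m)
    mid <- round(n / 2)
    edge <- max(which(m[mid, ]))
    m[mid, edge + seq_len(round(spikeUm / px))] <- TRUE
    m
}

# a noiseless NoiseParams
noiselessNoise <- function(bitDepth = 16L)
    NoiseParams(backgroundLevel = 0, photonScale = 0, gaussianSd = 0,
                psfSigmaUm = 0, bitDepth = bitDepth)

# majority ground-truth label under a segmented component (blur can push a
# component's first pixel just outside the true mask)
majorityLabel <- function(gtLabels, component) {
    v <- gtLabels[component]
    v <- v[v > 0]
    if (!length(v)) return(0L)
    as.integer(names(which.max(table(v))))
}
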