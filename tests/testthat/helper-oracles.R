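# Independent brute-force oracles and small fixture builders.

# all-pairs symmetric maximal Hausdorff distance over two vertex sets
hdBrute <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    max(max(apply(d, 1L, min)), max(apply(d, 2L, min)))
}

# per-voxel loop re-implementation of the sub-volume slab selection
cutBrute <- function(vol, axis, k, step_fraction = 0.05, n_levels = 10L) {
    fg <- voxels(vol)
    A <- worldAffine(vol)
    if (k == n_levels) return(fg)
    d <- dim(fg)
    out <- array(FALSE, d)
    half <- k * step_fraction * axis@length
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
        if (!fg[i, j, l]) next
        w <- A %*% c(i - 1, j - 1, l - 1, 1)
        p <- sum(axis@direction * w[1:3])
        out[i, j, l] <- abs(p - axis@center) <= half
    }
    out
}

# explicit sums-of-squares decomposition for the one-way RM ANOVA
rmAnovaBrute <- function(m) {
    n <- nrow(m); k <- ncol(m)
    gm <- mean(m)
    ss_sub <- 0
    for (i in seq_len(n)) ss_sub <- ss_sub + k * (mean(m[i, ]) - gm)^2
    ss_lev <- 0
    for (j in seq_len(k)) ss_lev <- ss_lev + n * (mean(m[, j]) - gm)^2
    ss_tot <- 0
    for (i in seq_len(n)) for (j in seq_len(k))
        ss_tot <- ss_tot + (m[i, j] - gm)^2
    ss_err <- ss_tot - ss_sub - ss_lev
    f <- (ss_lev / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
    list(ss_level = ss_lev, ss_error = ss_err, ss_subject = ss_sub, f = f)
}

# explicit two-way mean squares for the Shrout-Fleiss ICC forms
iccBrute <- function(m) {
    n <- nrow(m); k <- ncol(m)
    gm <- mean(m)
    bms <- 0
    for (i in seq_len(n)) bms <- bms + k * (mean(m[i, ]) - gm)^2
    bms <- bms / (n - 1)
    wms <- 0
    for (i in seq_len(n)) for (j in seq_len(k))
        wms <- wms + (m[i, j] - mean(m[i, ]))^2
    wms <- wms / (n * (k - 1))
    ems <- 0
    for (i in seq_len(n)) for (j in seq_len(k))
        ems <- ems + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + gm)^2
    ems <- ems / ((n - 1) * (k - 1))
    list(icc11 = (bms - wms) / (bms + (k - 1) * wms),
         icc31 = (bms - ems) / (bms + (k - 1) * ems),
         bms = bms, wms = wms, ems = ems)
}

# brute-force closest point over all triangles of a mesh (dense sampling of
# barycentric coordinates; adequate oracle for distances at coarse tolerance)
snapBrute <- function(p, mesh, n_grid = 60L) {
    v <- meshVertices(mesh)
    f <- meshFaces(mesh)
    best <- Inf
    u <- seq(0, 1, length.out = n_grid)
    for (t in seq_len(nrow(f))) {
        a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; c_ <- v[f[t, 3], ]
        for (l1 in u) for (l2 in u) {
            if (l1 + l2 > 1) next
            q <- a + l1 * (b - a) + l2 * (c_ - a)
            d <- sqrt(sum((p - q)^2))
            if (d < best) best <- d
        }
    }
    best
}

# small fast phantom used across tests
smallSpec <- function(kind = "straight_tube", seed = 1L, ...)
    phantomSpec(kind, length_mm = 48, max_radius_mm = 9, pixel_mm = 1.5,
                slice_mm = 4, seed = seed, ...)

smallAxis <- function(study) {
    att <- phantomAttachments(study)
    co <- landmarkCoords(att)
    makeAxis(co["origin", ], co["insertion", ])
}

# random blob mask: union of a few voxel balls, guaranteed nonempty
randomBlob <- function(dim = c(14, 14, 10), spacing = c(1, 1, 2),
                       n_balls = 3L) {
    ctr <- cbind(runif(n_balls, 4, dim[1] - 3),
                 runif(n_balls, 4, dim[2] - 3),
                 runif(n_balls, 2, dim[3] - 1))
    rad <- runif(n_balls, 2, 4)
    fg <- array(FALSE, dim)
    for (b in seq_len(n_balls)) {
        for (k in seq_len(dim[3])) {
            dz2 <- ((k - ctr[b, 3]) * spacing[3] / spacing[1])^2
            fg[, , k] <- fg[, , k] |
                (outer((seq_len(dim[1]) - ctr[b, 1])^2,
                       (seq_len(dim[2]) - ctr[b, 2])^2, `+`) + dz2 <=
                     rad[b]^2)
        }
    }
    labelVolume(fg, spacing = spacing)
}
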