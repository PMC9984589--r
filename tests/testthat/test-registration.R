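test_that("fitAffine recovers exact affines and reports zero residual", {
    set.seed(21)
    src <- matrix(rnorm(36, sd = 60), 12, 3)
    # identity
    fit0 <- fitAffine(src, src)
    expect_lt(max(abs(fit0@matrix - diag(3))), 1e-10)
    expect_lt(max(abs(fit0@translation)), 1e-8)
    expect_lt(attr(fit0, "rms"), 1e-8)

    # known shear + scale + translation
    K <- rbind(c(1.2, 0.3, 0), c(0, 0.9, -0.2), c(0.1, 0, 1.1))
    tv <- c(5, -7, 12)
    tgt <- sweep(src %*% t(K), 2, tv, `+`)
    fit <- fitAffine(src, tgt)
    expect_lt(max(abs(fit@matrix - K)), 1e-8)
    expect_lt(max(abs(fit@translation - tv)), 1e-8)

    # exactness property over random exact-affine instances
    for (i in 1:10) {
        n <- sample(4:12, 1)
        s <- matrix(rnorm(3 * n, sd = 40), n, 3)
        if (svd(scale(s, scale = FALSE))$d[3] < 1e-6 * max(svd(s)$d)) next
        A <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
        if (abs(det(A)) < 0.1) next
        t2 <- rnorm(3, sd = 10)
        f <- fitAffine(s, sweep(s %*% t(A), 2, t2, `+`))
        expect_lt(attr(f, "rms"), 1e-8)
    }
})

test_that("coplanar or collinear sources raise a degenerate-configuration error", {
    flat <- cbind(rnorm(6), rnorm(6), 0)
    expect_error(fitAffine(flat, flat), "coplanar|collinear")
    line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
    expect_error(fitAffine(line, line), "coplanar|collinear")
})

test_that("fit residual RMS is invariant under a common rigid motion", {
    set.seed(4)
    src <- matrix(rnorm(36, sd = 50), 12, 3)
    tgt <- src + matrix(rnorm(36, sd = 2), 12, 3)  # noisy correspondence
    rms0 <- attr(fitAffine(src, tgt), "rms")
    th <- 0.9
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    mv <- function(x) sweep(x %*% t(R), 2, c(30, -12, 7), `+`)
    rms1 <- attr(fitAffine(mv(src), mv(tgt)), "rms")
    expect_equal(rms0, rms1, tolerance = 1e-8)
})

test_that("transforms apply by name, compose and invert", {
    tr <- affineTransform(rbind(c(1.1, 0.2, 0), c(0, 0.95, 0.1),
                                c(-0.1, 0, 1.05)), c(1, 2, 3))
    expect_equal(applyTransform(tr, c(0, 0, 0)), c(1, 2, 3))
    id <- affineTransform(diag(3))
    p <- matrix(rnorm(15), 5, 3)
    expect_equal(applyTransform(id, p), p)
    back <- applyTransform(tr, applyTransform(invertTransform(tr), p))
    expect_lt(max(abs(back - p)), 1e-9)

    # name-based pairing ignores file order
    set.seed(2)
    co <- matrix(rnorm(36, sd = 30), 12, 3)
    src <- landmarkSet(paste0("L", 1:12), co)
    perm <- sample(12)
    tgt <- landmarkSet(paste0("L", perm),
                       applyTransform(tr, co)[perm, ])
    fit <- fitAffine(src, tgt)
    expect_lt(max(abs(fit@matrix - tr@matrix)), 1e-8)
})

test_that("fitSimilarity recovers rotation + scale + translation", {
    set.seed(31)
    src <- matrix(rnorm(36, sd = 40), 12, 3)
    th <- 0.5
    R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
    s <- 1.07
    tgt <- sweep(src %*% t(s * R), 2, c(4, 5, -6), `+`)
    fit <- fitSimilarity(src, tgt)
    expect_lt(max(abs(fit@matrix - s * R)), 1e-8)
    expect_lt(attr(fit, "rms"), 1e-8)
})

test_that("snapToSurface matches a brute-force closest-point search", {
    # unit square in the z=0 plane
    sq <- surfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3), c(1, 3, 4)))
    hit <- snapToSurface(c(0, 0, 5), sq)
    expect_equal(as.numeric(hit), c(0, 0, 0))
    expect_equal(attr(hit, "distance"), 5)
    expect_true(attr(hit, "snapped"))

    # point on a vertex: unchanged, flag false
    v0 <- snapToSurface(c(1, 1, 0), sq)
    expect_equal(as.numeric(v0), c(1, 1, 0))
    expect_false(attr(v0, "snapped"))

    # beyond max_snap_mm: unchanged with a warning
    expect_warning(far <- snapToSurface(c(0, 0, 100), sq, max_snap_mm = 10),
                   "unchanged")
    expect_equal(as.numeric(far), c(0, 0, 100))

    # oracle equivalence on a real mesh
    set.seed(12)
    mesh <- maskToSurface(randomBlob(dim = c(9, 9, 6)))
    for (i in 1:5) {
        p <- rnorm(3, sd = 8) + c(5, 5, 5)
        got <- snapToSurface(p, mesh, max_snap_mm = 1e6)
        expect_equal(attr(got, "distance"), snapBrute(p, mesh),
                     tolerance = 2e-2)
    }
    expect_error(snapToSurface(c(0, 0, 0),
                               new("SurfaceMesh",
                                   vertices = matrix(numeric(0), 0, 3),
                                   faces = matrix(integer(0), 0, 3))))
})

test_that("transform JSON serialization round-trips exactly", {
    tr <- affineTransform(matrix(rnorm(9), 3, 3) + diag(3), rnorm(3))
    f <- withr::local_tempfile(fileext = ".json")
    writeTransform(tr, f)
    back <- readTransform(f)
    expect_identical(back@matrix, tr@matrix)
    expect_identical(back@translation, tr@translation)
})
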