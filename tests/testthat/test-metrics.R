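test_that("jaccard handles identity, disjoint and hand-counted overlap", {
    fg <- array(FALSE, c(6, 4, 4))
    fg[2:3, 2:3, 2:3] <- TRUE          # 2x2x2 cube
    a <- labelVolume(fg)
    expect_equal(jaccard(a, a), 1)

    fg2 <- array(FALSE, c(6, 4, 4))
    fg2[3:4, 2:3, 2:3] <- TRUE         # shifted 1 voxel along x
    b <- labelVolume(fg2)
    expect_equal(jaccard(a, b), 1 / 3) # |I| = 4, |U| = 12

    fg3 <- array(FALSE, c(6, 4, 4))
    fg3[5:6, 2:3, 2:3] <- TRUE
    expect_equal(jaccard(a, labelVolume(fg3)), 0)

    expect_error(jaccard(a, labelVolume(array(TRUE, c(3, 3, 3)))),
                 "mismatch")
    shifted_aff <- diag(4); shifted_aff[1, 4] <- 1
    expect_error(jaccard(a, labelVolume(fg, affine = shifted_aff)),
                 "mismatch")
    empty <- labelVolume(array(FALSE, c(6, 4, 4)))
    expect_error(jaccard(empty, empty), "empty")
})

test_that("hausdorffMax reproduces hand-computed distances and symmetry", {
    tri <- function(v) surfaceMesh(v, matrix(1:3, 1))
    a <- tri(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
    expect_equal(hausdorffMax(a, a), 0)

    # near-point sets: tiny valid triangles standing in for single vertices
    eps <- 1e-5
    pt <- function(p) surfaceMesh(rbind(p, p + c(eps, 0, 0),
                                        p + c(0, eps, 0)),
                                  matrix(1:3, 1))
    expect_equal(hausdorffMax(pt(c(0, 0, 0)), pt(c(3, 4, 0))), 5,
                 tolerance = 1e-4)

    A <- surfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)),
                     matrix(1:3, 1))
    B <- surfaceMesh(rbind(c(0, 0, 0), c(0, 2, 0), c(0, 0, 1)),
                     matrix(1:3, 1))
    # vertex sets {(0,0,0),(1,0,0),(0,0,~1)} vs {(0,0,0),(0,2,0),(0,0,1)}
    expect_equal(hausdorffMax(A, B), 2, tolerance = 1e-6)
    expect_equal(hausdorffMax(B, A), hausdorffMax(A, B))
})

test_that("accelerated Hausdorff equals all-pairs brute force", {
    set.seed(23)
    for (i in 1:10) {
        a <- maskToSurface(randomBlob())
        b <- maskToSurface(randomBlob())
        expect_identical(hausdorffMax(a, b),
                         hdBrute(meshVertices(a), meshVertices(b)))
        expect_identical(hausdorffMax(a, b), hausdorffMax(b, a))
    }
})

test_that("JI is scale-invariant and HD scale-equivariant", {
    set.seed(9)
    v1 <- randomBlob(); v2 <- randomBlob()
    s <- 2.5
    scale_vol <- function(v) labelVolume(voxels(v),
                                         affine = diag(c(s, s, s, 1)) %*%
                                             worldAffine(v))
    expect_equal(jaccard(v1, v2), jaccard(scale_vol(v1), scale_vol(v2)))
    expect_equal(hausdorffMax(maskToSurface(scale_vol(v1)),
                              maskToSurface(scale_vol(v2))),
                 s * hausdorffMax(maskToSurface(v1), maskToSurface(v2)),
                 tolerance = 1e-12)
})

test_that("normalizedVolumeVariance implements sample variance over mean", {
    expect_equal(normalizedVolumeVariance(c(90, 100, 110)), 100)
    expect_equal(normalizedVolumeVariance(c(5, 5, 5)), 0)
    expect_equal(normalizedVolumeVariance(c(320, 320)), 0)
    expect_error(normalizedVolumeVariance(c(100)), "at least 2")
    expect_error(normalizedVolumeVariance(c(100, -1)), "positive")
    expect_equal(volumeCV(c(90, 100, 110)), 10)
})

test_that("compareRepeats averages all unordered repeat pairs per level", {
    st <- makePhantom(smallSpec())
    ax <- smallAxis(st)
    s <- cutSeries(st@truth, ax)

    # identical repeats: JI 1, HD 0, nVV 0 at every level
    rec <- compareRepeats(list(s, s, s), "p1", "gluteus_medius")
    expect_equal(nrow(rec), 10L)
    expect_equal(rec$ji_mean, rep(1, 10))
    expect_equal(rec$hd_mean_mm, rep(0, 10))
    expect_equal(rec$nvv_percent, rep(0, 10))
    expect_equal(rec$n_pairs, rep(3L, 10))
    expect_equal(lengths(rec$pairwise_ji), rep(3L, 10))

    # two repeats: one pair, means equal the single value
    noisy <- simulateRepeats(st@truth, ax,
                             noiseModel(belly_sigma_mm = 1,
                                        extremity_sigma_mm = 1,
                                        end_slice_dropout_prob = 0,
                                        seed = 5), 2)
    s2 <- lapply(noisy, cutSeries, axis = ax)
    rec2 <- compareRepeats(s2, "p1", "iliopsoas")
    expect_equal(lengths(rec2$pairwise_ji), rep(1L, 10))
    expect_equal(rec2$ji_mean, vapply(rec2$pairwise_ji, mean, numeric(1)))
    expect_equal(rec2$hd_mean_mm,
                 vapply(rec2$pairwise_hd_mm, mean, numeric(1)))
})

test_that("a level empty in any repeat is flagged and excluded", {
    st <- makePhantom(smallSpec())
    ax <- smallAxis(st)
    s <- cutSeries(st@truth, ax)
    # a repeat with a missed innermost contour can only be represented by
    # hand (cutSeries itself refuses an empty central slab)
    empty1 <- labelVolume(array(FALSE, dim(voxels(st@truth))),
                          affine = worldAffine(st@truth))
    s2 <- new("SubvolumeSeries",
              levels = c(list(empty1), s@levels[-1]),
              levelPercent = s@levelPercent, axis = s@axis)
    expect_warning(rec <- compareRepeats(list(s, s2), "p1",
                                         "gluteus_medius"),
                   "flagged")
    expect_true(rec$excluded[1])
    expect_true(is.na(rec$ji_mean[1]))
    expect_false(any(rec$excluded[-1]))
})
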