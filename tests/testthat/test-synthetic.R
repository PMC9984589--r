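test_that("phantom rasterization matches the analytic cylinder volume", {
    spec <- phantomSpec("straight_tube", length_mm = 100, max_radius_mm = 15,
                        pixel_mm = 0.8, slice_mm = 4)
    st <- makePhantom(spec)
    expect_equal(volumeMm3(st@truth), pi * 15^2 * 100, tolerance = 0.05)

    # single 6-connected component
    lab <- repseg:::cppLabelComponents(as.vector(voxels(st@truth)),
                                       dim(voxels(st@truth)))
    expect_equal(attr(lab, "ncomp"), 1L)

    # attachments on the centerline ends, 12 landmarks
    co <- landmarkCoords(phantomAttachments(st))
    expect_equal(unname(co["insertion", ]), c(0, 0, 0), tolerance = 1e-9)
    expect_equal(unname(co["origin", ]), c(0, 0, 100), tolerance = 1e-9)
    expect_length(st@landmarks, 12L)
})

test_that("phantom generation is deterministic and taper shrinks extremities", {
    s1 <- makePhantom(smallSpec(seed = 5))
    s2 <- makePhantom(smallSpec(seed = 5))
    expect_identical(voxels(s1@truth), voxels(s2@truth))
    expect_identical(s1@trueAffine@matrix, s2@trueAffine@matrix)

    tp <- makePhantom(smallSpec("tapered_tube", taper = 0.9))
    areas <- apply(voxels(tp@truth), 3, sum)
    areas <- areas[areas > 0]
    expect_true(all(areas <= areas[ceiling(length(areas) / 2)]))
})

test_that("an explicit grid too small is rejected with the required size", {
    spec <- smallSpec()
    spec$grid_dim <- c(5, 5, 5)
    expect_error(makePhantom(spec), "need at least \\(2[0-9], ")
    need <- repseg:::.required_grid(spec)
    spec$grid_dim <- need + 2L
    expect_s4_class(makePhantom(spec)@truth, "LabelVolume")
})

test_that("zero-noise repeats are identical to the truth", {
    st <- makePhantom(smallSpec())
    ax <- smallAxis(st)
    reps <- simulateRepeats(st@truth, ax,
                            noiseModel(0, 0, 10, 0, seed = 1), 3)
    expect_length(reps, 3L)
    for (r in reps) expect_identical(voxels(r), voxels(st@truth))
})

test_that("repeats are reproducible, share the grid and stay connected", {
    st <- makePhantom(smallSpec())
    ax <- smallAxis(st)
    nm <- noiseModel(belly_sigma_mm = 0.5, extremity_sigma_mm = 3,
                     end_slice_dropout_prob = 0.3, seed = 9)
    r1 <- suppressMessages(simulateRepeats(st@truth, ax, nm, 3))
    r2 <- suppressMessages(simulateRepeats(st@truth, ax, nm, 3))
    expect_length(r1, 3L)
    for (i in 1:3) {
        expect_identical(voxels(r1[[i]]), voxels(r2[[i]]))
        expect_identical(dim(voxels(r1[[i]])), dim(voxels(st@truth)))
        lab <- repseg:::cppLabelComponents(as.vector(voxels(r1[[i]])),
                                           dim(voxels(r1[[i]])))
        expect_equal(attr(lab, "ncomp"), 1L)
    }
    # repeats differ from each other (noise actually applied)
    expect_false(identical(voxels(r1[[1]]), voxels(r1[[2]])))
})

test_that("registration recovers the generating atlas affine exactly", {
    for (seed in c(2, 7, 19)) {
        st <- makePhantom(smallSpec(seed = seed))
        fit <- fitAffine(st@atlasLandmarks, st@landmarks)
        expect_lt(max(abs(fit@matrix - st@trueAffine@matrix)), 1e-8)
        expect_lt(max(abs(fit@translation - st@trueAffine@translation)),
                  1e-8)
    }
})

test_that("mean JI degrades monotonically with belly noise", {
    sigmas <- c(0.2, 1.2, 3)
    mean_ji <- vapply(seq_along(sigmas), function(si) {
        jis <- vapply(1:20, function(p) {
            st <- makePhantom(smallSpec(seed = 100 + p))
            ax <- smallAxis(st)
            nm <- noiseModel(belly_sigma_mm = sigmas[si],
                             extremity_sigma_mm = sigmas[si],
                             end_slice_dropout_prob = 0,
                             seed = 1000 * si + p)
            reps <- suppressMessages(simulateRepeats(st@truth, ax, nm, 2))
            jaccard(reps[[1]], reps[[2]])
        }, numeric(1))
        mean(jis)
    }, numeric(1))
    expect_gt(mean_ji[1], mean_ji[2])
    expect_gt(mean_ji[2], mean_ji[3])
})

test_that("study bundles round-trip through disk and record their spec", {
    st <- makePhantom(smallSpec(seed = 3))
    ax <- smallAxis(st)
    st@repeats <- suppressMessages(simulateRepeats(
        st@truth, ax, noiseModel(seed = 3), 2))
    dir <- withr::local_tempdir()
    manifest <- writeStudy(st, file.path(dir, "study"))
    back <- readStudy(file.path(dir, "study"))
    expect_identical(voxels(back@truth), voxels(st@truth))
    for (i in seq_along(st@repeats))
        expect_identical(voxels(back@repeats[[i]]),
                         voxels(st@repeats[[i]]))
    expect_lt(max(abs(landmarkCoords(back@landmarks) -
                          landmarkCoords(st@landmarks))), 1e-9)
    expect_identical(back@trueAffine@matrix, st@trueAffine@matrix)

    # regeneration from the recorded spec + seed reproduces the truth
    spec2 <- do.call(phantomSpec, back@spec[setdiff(names(back@spec),
                                                    "grid_dim")])
    regen <- makePhantom(spec2)
    expect_identical(voxels(regen@truth), voxels(back@truth))

    # refuse to clobber a non-empty directory without overwrite
    expect_error(writeStudy(st, file.path(dir, "study")), "not empty")
    expect_silent(writeStudy(st, file.path(dir, "study"),
                             overwrite = TRUE))

    # unwritable target fails loudly
    expect_error(writeStudy(st, "/proc/1/repseg_study"), "cannot")
})
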