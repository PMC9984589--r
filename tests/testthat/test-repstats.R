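test_that("normality gate routes clean and pathological data correctly", {
    # null: normal columns should pass the gate most of the time
    parametric_hits <- 0L
    for (r in 1:60) {
        m <- withr::with_seed(1000 + r, matrix(rnorm(50 * 5), 50, 5))
        if (normalityGate(m)$branch == "parametric")
            parametric_hits <- parametric_hits + 1L
    }
    expect_gte(parametric_hits / 60, 0.6)  # (1 - alpha)^5 ~ 0.77 expected

    # heavy tails: Cauchy columns should fail the gate nearly always
    nonpar_hits <- 0L
    for (r in 1:30) {
        m <- withr::with_seed(2000 + r, matrix(rt(50 * 5, df = 1), 50, 5))
        if (normalityGate(m)$branch == "nonparametric")
            nonpar_hits <- nonpar_hits + 1L
    }
    expect_gte(nonpar_hits / 30, 0.9)

    # constant column forces the nonparametric branch
    m <- withr::with_seed(1, matrix(rnorm(30), 10, 3))
    m[, 2] <- 7
    expect_message(g <- normalityGate(m), "nonparametric")
    expect_equal(g$branch, "nonparametric")
})

test_that("rmAnova matches the explicit sums-of-squares oracle", {
    m <- rbind(c(5.1, 6.2, 7.9), c(4.8, 6.8, 8.1),
               c(5.5, 5.9, 7.2), c(4.9, 6.5, 8.4))
    got <- rmAnova(m)
    ora <- rmAnovaBrute(m)
    expect_equal(got$ss_level, ora$ss_level, tolerance = 1e-9)
    expect_equal(got$ss_error, ora$ss_error, tolerance = 1e-9)
    expect_equal(got$ss_subject, ora$ss_subject, tolerance = 1e-9)
    expect_equal(got$statistic, ora$f, tolerance = 1e-9)
    expect_equal(got$df, c(2, 6))

    set.seed(42)
    for (i in 1:5) {
        m2 <- matrix(rnorm(8 * 4, sd = 2), 8, 4) + rnorm(8, sd = 3)
        got2 <- rmAnova(m2)
        ora2 <- rmAnovaBrute(m2)
        expect_equal(got2$statistic, ora2$f, tolerance = 1e-9)
    }

    # pure subject offsets: no level effect, F defined as 0
    m3 <- matrix(rep(c(1, 5, 9, 2), 3), 4, 3)
    got3 <- rmAnova(m3)
    expect_equal(got3$statistic, 0)
    expect_equal(got3$p_value, 1)

    # strong injected level effect is detected
    m4 <- withr::with_seed(7, matrix(rnorm(20 * 3), 20, 3) +
                               matrix(rep(c(0, 3, 6), each = 20), 20, 3))
    expect_lt(rmAnova(m4)$p_value, 0.001)
})

test_that("rmAnova and friedman are invariant under subject relabeling", {
    m <- withr::with_seed(3, matrix(rnorm(12 * 5), 12, 5))
    perm <- withr::with_seed(4, sample(12))
    expect_equal(rmAnova(m)$statistic, rmAnova(m[perm, ])$statistic)
    expect_equal(friedmanLevels(m)$statistic,
                 friedmanLevels(m[perm, ])$statistic)
})

test_that("friedman reproduces the hand-computed identical-ranking statistic", {
    m <- rbind(c(1, 2, 3), c(4, 6, 8), c(0.1, 0.5, 0.9))
    got <- friedmanLevels(m)
    expect_equal(got$statistic, 6)  # rank sums 3, 6, 9 with n = k = 3
    expect_equal(got$df, 2)

    expect_warning(flat <- friedmanLevels(matrix(2, 5, 4)), "constant")
    expect_equal(flat$statistic, 0)
    expect_equal(flat$p_value, 1)
})

test_that("friedman type-I error is near nominal under the permuted null", {
    rej <- 0L
    n_rep <- 400L
    base <- withr::with_seed(99, matrix(rnorm(50 * 5), 50, 5))
    for (r in seq_len(n_rep)) {
        m <- withr::with_seed(3000 + r,
                              t(apply(base, 1, sample)))
        if (friedmanLevels(m)$p_value < 0.05) rej <- rej + 1L
    }
    expect_gte(rej / n_rep, 0.02)
    expect_lte(rej / n_rep, 0.08)
})

test_that("posthoc pairwise tests apply Bonferroni over the full pair family", {
    m <- withr::with_seed(5, matrix(rnorm(15 * 10), 15, 10))
    ph <- posthocPairwise(m, "parametric")
    expect_equal(ph$m_comparisons, 45L)
    expect_true(isSymmetric(unname(ph$p_adjusted)))
    expect_equal(ph$p_adjusted, ifelse(is.na(ph$p_raw), NA,
                                       pmin(1, 45 * ph$p_raw)))
    expect_true(all(is.na(diag(ph$p_adjusted))))

    # identical columns: adjusted p = 1 for that pair
    m2 <- withr::with_seed(6, matrix(rnorm(10 * 3), 10, 3))
    m2[, 2] <- m2[, 1]
    ph2 <- posthocPairwise(m2, "nonparametric")
    expect_equal(ph2$p_adjusted[1, 2], 1)

    # monotone in raw p and capped at 1
    ord <- order(ph$p_raw[upper.tri(ph$p_raw)])
    adj <- ph$p_adjusted[upper.tri(ph$p_adjusted)][ord]
    expect_true(all(diff(adj) >= 0))
    expect_true(all(adj <= 1))
})

test_that("posthoc familywise error stays at or below alpha under the null", {
    fam_err <- 0L
    n_rep <- 150L
    for (r in seq_len(n_rep)) {
        m <- withr::with_seed(5000 + r, matrix(rnorm(40 * 5), 40, 5))
        ph <- posthocPairwise(m, "parametric")
        if (any(ph$p_adjusted < 0.05, na.rm = TRUE)) fam_err <- fam_err + 1L
    }
    expect_lte(fam_err / n_rep, 0.05 + 2.5 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("iccAgreement matches explicit mean squares and recovers truth", {
    m <- rbind(c(9, 2, 5), c(6, 1, 7), c(8, 4, 6),
               c(7, 1, 2), c(10, 5, 6), c(6, 2, 4))
    # strong rater offsets make ICC(1,1) negative here; the warning is the
    # documented behaviour and is asserted separately below
    got <- suppressWarnings(iccAgreement(m))
    ora <- iccBrute(m)
    expect_equal(got$icc11, ora$icc11, tolerance = 1e-12)
    expect_equal(got$icc31, ora$icc31, tolerance = 1e-12)
    expect_equal(got$bms, ora$bms, tolerance = 1e-12)
    expect_equal(got$ems, ora$ems, tolerance = 1e-12)
    # point estimates inside their confidence intervals
    expect_gte(got$icc11, got$icc11_ci[1])
    expect_lte(got$icc11, got$icc11_ci[2])
    expect_gte(got$icc31, got$icc31_ci[1])
    expect_lte(got$icc31, got$icc31_ci[2])

    # identical raters: ICC(3,1) = 1
    m2 <- matrix(rnorm(8), 8, 1)[, c(1, 1, 1)]
    expect_equal(iccAgreement(m2)$icc31, 1)

    # parameter recovery: sigma_b^2 = 9, sigma_w^2 = 1 -> ICC(1,1) = 0.9
    m3 <- withr::with_seed(11, {
        subj <- rnorm(100, sd = 3)
        matrix(subj, 100, 3) + matrix(rnorm(300), 100, 3)
    })
    expect_lt(abs(iccAgreement(m3)$icc11 - 0.9), 0.05)

    # no between-subject variance, strong rater offsets: negative estimate
    m4 <- matrix(rep(c(0, 5, 10), each = 5), 5, 3) +
        withr::with_seed(21, matrix(rnorm(15, sd = 0.01), 5, 3))
    expect_warning(neg <- iccAgreement(m4), "non-positive")
    expect_lt(neg$icc11, 0)
})

test_that("testLevels gates, tests and reports coherently", {
    m <- withr::with_seed(13, matrix(rnorm(20 * 4), 20, 4) +
                              matrix(rep(c(0, 0.5, 1, 1.5), each = 20),
                                     20, 4))
    rep_ <- testLevels(m)
    expect_s3_class(rep_, "TestReport")
    expect_true(rep_$branch %in% c("parametric", "nonparametric"))
    expect_lt(rep_$omnibus_p, 0.05)
    expect_equal(dim(rep_$posthoc), c(4, 4))
    expect_output(print(rep_), "TestReport")
})
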