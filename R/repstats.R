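#' Build a subjects-by-levels metric matrix
#'
#' Reshapes the tidy per-level metric table from [compareRepeats()] into the
#' subjects x levels matrix the statistical layer consumes. Subjects with
#' any flagged/missing level are dropped listwise; the number dropped is
#' reported via attribute \code{n_dropped} and a message.
#'
#' @param metrics a data.frame as returned by [compareRepeats()] (rows from
#'   several subjects concatenated), already restricted to one muscle.
#' @param metric one of \code{"ji_mean"}, \code{"hd_mean_mm"},
#'   \code{"nvv_percent"}.
#' @return a numeric matrix, rownames subjects, colnames level percentages.
#' @export
metricMatrix <- function(metrics,
                         metric = c("ji_mean", "hd_mean_mm", "nvv_percent")) {
    metric <- match.arg(metric)
    lv <- sort(unique(metrics$level_percent))
    sub <- unique(metrics$subject)
    m <- matrix(NA_real_, length(sub), length(lv),
                dimnames = list(sub, lv))
    m[cbind(match(metrics$subject, sub),
            match(metrics$level_percent, lv))] <- metrics[[metric]]
    keep <- rowSums(is.na(m)) == 0L
    if (any(!keep))
        message(sum(!keep), " subject(s) dropped listwise (missing levels)")
    out <- m[keep, , drop = FALSE]
    attr(out, "metric") <- metric
    attr(out, "n_dropped") <- sum(!keep)
    out
}

#' Normality gate for the repeated-measures branch
#'
#' Applies a Shapiro-Wilk test to every level column; the parametric branch
#' (RM-ANOVA + paired t) is taken only if every column passes at
#' \code{alpha}, otherwise the nonparametric branch (Friedman + Wilcoxon).
#' A constant column forces the nonparametric branch.
#'
#' @param m subjects x levels numeric matrix (>= 3 subjects).
#' @param alpha significance level for each column test (default 0.05).
#' @return a list with \code{branch} ("parametric"/"nonparametric"),
#'   \code{p_values} per column and \code{alpha}.
#' @export
normalityGate <- function(m, alpha = 0.05) {
    m <- as.matrix(m)
    if (nrow(m) < 3L)
        stop("normality testing needs at least 3 subjects")
    pv <- apply(m, 2L, function(col) {
        if (stats::sd(col) == 0) return(NA_real_)
        stats::shapiro.test(col)$p.value
    })
    if (anyNA(pv)) {
        message("constant column(s) ",
                paste(colnames(m)[is.na(pv)], collapse = ", "),
                ": nonparametric branch forced")
        branch <- "nonparametric"
    } else {
        branch <- if (all(pv > alpha)) "parametric" else "nonparametric"
    }
    list(branch = branch, p_values = pv, alpha = alpha)
}

#' One-way repeated-measures ANOVA across levels
#'
#' Within-subject one-way ANOVA with subjects as blocks:
#' F = MS_level / MS_error on (k - 1, (n - 1)(k - 1)) degrees of freedom,
#' fitted through \code{stats::aov} with an \code{Error(subject)} stratum.
#' When both the level and error sums of squares vanish (identical columns)
#' the statistic is defined as 0 with p = 1.
#'
#' @param m subjects x levels numeric matrix (>= 3 subjects, >= 2 levels).
#' @return a list with \code{statistic} (F), \code{p_value}, \code{df}, and
#'   the sums of squares \code{ss_level}, \code{ss_error}, \code{ss_subject}.
#' @export
rmAnova <- function(m) {
    m <- as.matrix(m)
    n <- nrow(m); k <- ncol(m)
    if (k < 2L) stop("need at least 2 levels")
    if (n < 3L) stop("need at least 3 subjects")
    df <- data.frame(y = as.vector(m),
                     subject = factor(rep(seq_len(n), times = k)),
                     level = factor(rep(seq_len(k), each = n)))
    fit <- stats::aov(y ~ level + Error(subject), data = df)
    tab <- summary(fit)[["Error: Within"]][[1L]]
    ss_level <- tab["level", "Sum Sq"]
    ss_error <- tab["Residuals", "Sum Sq"]
    ss_subject <- summary(fit)[["Error: subject"]][[1L]]["Residuals", "Sum Sq"]
    df1 <- k - 1L; df2 <- (n - 1L) * (k - 1L)
    if (ss_level <= .Machine$double.eps * sum(m^2) && ss_error <=
        .Machine$double.eps * sum(m^2)) {
        f <- 0; p <- 1
    } else {
        f <- (ss_level / df1) / (ss_error / df2)
        p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    }
    list(statistic = unname(f), p_value = unname(p), df = c(df1, df2),
         ss_level = unname(ss_level), ss_error = unname(ss_error),
         ss_subject = unname(ss_subject))
}

#' Friedman test across levels
#'
#' Rank-based repeated-measures omnibus test (midrank ties), the
#' nonparametric counterpart of [rmAnova()]. Delegates to
#' \code{stats::friedman.test}; an all-tied matrix returns statistic 0 and
#' p = 1 with a warning.
#'
#' @param m subjects x levels numeric matrix (>= 3 subjects).
#' @return a list with \code{statistic} (chi-squared), \code{p_value} and
#'   \code{df}.
#' @export
friedmanLevels <- function(m) {
    m <- as.matrix(m)
    if (nrow(m) < 3L) stop("need at least 3 subjects")
    if (all(apply(m, 1L, function(r) length(unique(r)) == 1L))) {
        warning("all rows are constant: Friedman statistic 0, p = 1")
        return(list(statistic = 0, p_value = 1, df = ncol(m) - 1L))
    }
    ft <- stats::friedman.test(m)
    list(statistic = unname(ft$statistic), p_value = ft$p.value,
         df = unname(ft$parameter))
}

#' Post hoc pairwise level comparisons with Bonferroni correction
#'
#' Tests every unordered pair of levels (all C(k, 2) pairs, 45 for ten
#' levels) with a paired t-test (parametric branch) or Wilcoxon signed-rank
#' test (nonparametric branch; zero differences discarded, midrank ties,
#' normal approximation), and applies a Bonferroni correction over the full
#' pair family: p_adj = min(1, m * p). A pair with a zero-variance
#' difference vector gets p = 1.
#'
#' @param m subjects x levels numeric matrix.
#' @param branch \code{"parametric"} or \code{"nonparametric"} (e.g. from
#'   [normalityGate()]).
#' @return a list with symmetric matrices \code{p_adjusted} and \code{p_raw}
#'   (NA diagonal), \code{branch} and family size \code{m_comparisons}.
#' @export
posthocPairwise <- function(m, branch = c("parametric", "nonparametric")) {
    branch <- match.arg(branch)
    m <- as.matrix(m)
    k <- ncol(m)
    pairs <- utils::combn(k, 2L)
    nm <- ncol(pairs)
    praw <- numeric(nm)
    for (q in seq_len(nm)) {
        a <- m[, pairs[1L, q]]; b <- m[, pairs[2L, q]]
        d <- a - b
        if (stats::sd(d) == 0) {
            praw[q] <- 1
        } else if (branch == "parametric") {
            praw[q] <- stats::t.test(a, b, paired = TRUE)$p.value
        } else {
            praw[q] <- suppressWarnings(
                stats::wilcox.test(a, b, paired = TRUE,
                                   exact = FALSE, correct = TRUE)$p.value)
        }
    }
    padj <- stats::p.adjust(praw, method = "bonferroni", n = nm)
    toMat <- function(p) {
        M <- matrix(NA_real_, k, k, dimnames = list(colnames(m),
                                                    colnames(m)))
        M[t(pairs)] <- p
        M[t(pairs)[, 2:1, drop = FALSE]] <- p
        M
    }
    list(p_adjusted = toMat(padj), p_raw = toMat(praw), branch = branch,
         m_comparisons = nm)
}

#' Intraclass correlation coefficients ICC(1,1) and ICC(3,1)
#'
#' Single-rater intraclass correlation from the Shrout-Fleiss ANOVA mean
#' squares: ICC(1,1) = (BMS - WMS) / (BMS + (k - 1) WMS) from the one-way
#' random model, and ICC(3,1) = (BMS - EMS) / (BMS + (k - 1) EMS) from the
#' two-way mixed model, with F-based 95% confidence intervals. Negative
#' estimates (zero between-subject variance) are returned as-is with a
#' warning, not clamped.
#'
#' @param values subjects x raters numeric matrix, no missing cells,
#'   >= 5 subjects and >= 2 raters.
#' @param conf confidence level for the intervals (default 0.95).
#' @return a list with \code{icc11}, \code{icc31}, their confidence
#'   intervals \code{icc11_ci}, \code{icc31_ci}, \code{n_subjects},
#'   \code{n_raters} and the mean squares \code{bms}, \code{wms}, \code{ems}.
#' @export
iccAgreement <- function(values, conf = 0.95) {
    m <- as.matrix(values)
    n <- nrow(m); k <- ncol(m)
    if (n < 5L) stop("ICC needs at least 5 subjects")
    if (k < 2L) stop("ICC needs at least 2 raters")
    if (anyNA(m)) stop("ICC input must have no missing cells")
    gm <- mean(m)
    rm_ <- rowMeans(m); cm <- colMeans(m)
    bms <- k * sum((rm_ - gm)^2) / (n - 1L)
    wms <- sum(sweep(m, 1L, rm_)^2) / (n * (k - 1L))
    jms <- n * sum((cm - gm)^2) / (k - 1L)
    ems <- (sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)) /
        ((n - 1L) * (k - 1L))
    icc11 <- (bms - wms) / (bms + (k - 1L) * wms)
    icc31 <- (bms - ems) / (bms + (k - 1L) * ems)
    if (icc11 <= 0 || icc31 <= 0)
        warning("non-positive ICC estimate: between-subject variance is not above the within-subject variance")
    a2 <- (1 - conf) / 2
    ci_from_F <- function(Fobs, df2) {
        FL <- Fobs / stats::qf(1 - a2, n - 1L, df2)
        FU <- Fobs * stats::qf(1 - a2, df2, n - 1L)
        c((FL - 1) / (FL + (k - 1L)), (FU - 1) / (FU + (k - 1L)))
    }
    list(icc11 = icc11, icc31 = icc31,
         icc11_ci = ci_from_F(bms / wms, n * (k - 1L)),
         icc31_ci = ci_from_F(bms / ems, (n - 1L) * (k - 1L)),
         n_subjects = n, n_raters = k,
         bms = bms, wms = wms, jms = jms, ems = ems, conf = conf)
}

#' Run the full normality-gated statistical comparison for one metric
#'
#' Gate, omnibus (RM-ANOVA or Friedman) and Bonferroni-corrected post hoc
#' pairwise tests for one subjects x levels matrix, at significance level
#' \code{alpha}.
#'
#' @param m subjects x levels numeric matrix.
#' @param alpha significance level (default 0.05).
#' @return a \code{TestReport} list: \code{branch}, \code{omnibus_stat},
#'   \code{omnibus_p}, \code{posthoc} (adjusted p matrix), \code{gate}
#'   (per-level normality p-values) and \code{alpha}.
#' @export
testLevels <- function(m, alpha = 0.05) {
    gate <- normalityGate(m, alpha)
    omni <- if (gate$branch == "parametric") rmAnova(m) else
        suppressWarnings(friedmanLevels(m))
    ph <- posthocPairwise(m, gate$branch)
    structure(list(branch = gate$branch,
                   omnibus_stat = omni$statistic,
                   omnibus_p = omni$p_value,
                   posthoc = ph$p_adjusted,
                   posthoc_raw = ph$p_raw,
                   gate = gate$p_values,
                   alpha = alpha),
              class = "TestReport")
}

#' @export
print.TestReport <- function(x, ...) {
    cat(sprintf("TestReport: %s branch; omnibus stat %.4f, p %.4g (alpha %.2f)\n",
                x$branch, x$omnibus_stat, x$omnibus_p, x$alpha))
    sig <- sum(x$posthoc[upper.tri(x$posthoc)] < x$alpha, na.rm = TRUE)
    cat(sprintf("  %d of %d post hoc pairs significant after Bonferroni\n",
                sig, sum(upper.tri(x$posthoc))))
    invisible(x)
}
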