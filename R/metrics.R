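#' Jaccard index of two label volumes
#'
#' Voxel-wise overlap |A intersect B| / |A union B| between two masks on an
#' identical grid (shape and affine within 1e-6). Symmetric, in [0, 1];
#' computed natively on the masks.
#'
#' @param a,b [LabelVolume-class] objects on the same grid; at least one
#'   must be nonempty.
#' @return the Jaccard index.
#' @examples
#' v <- labelVolume(array(1, c(2, 2, 2)))
#' jaccard(v, v)  # 1
#' @export
jaccard <- function(a, b) {
    stopifnot(is(a, "LabelVolume"), is(b, "LabelVolume"))
    if (!identical(dim(a@voxels), dim(b@voxels)))
        stop("grid mismatch: shapes (", paste(dim(a@voxels), collapse = ","),
             ") vs (", paste(dim(b@voxels), collapse = ","), ")")
    if (max(abs(a@affine - b@affine)) > 1e-6)
        stop("grid mismatch: affines differ by more than 1e-6")
    uni <- sum(a@voxels | b@voxels)
    if (uni == 0L)
        stop("Jaccard index undefined: both masks are empty")
    sum(a@voxels & b@voxels) / uni
}

#' Maximal (symmetric) Hausdorff distance between two surfaces
#'
#' The worst-case surface disagreement in mm: the larger of the two directed
#' maximum nearest-neighbour distances between the vertex sets of the two
#' meshes. Computed with a sorted-coordinate early-exit search that is exact
#' (identical to the all-pairs brute force).
#'
#' @param a,b nonempty [SurfaceMesh-class] objects.
#' @return the maximal Hausdorff distance in mm.
#' @examples
#' m1 <- surfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), c(1, 2, 3))
#' hausdorffMax(m1, m1)  # 0
#' @export
hausdorffMax <- function(a, b) {
    stopifnot(is(a, "SurfaceMesh"), is(b, "SurfaceMesh"))
    if (nrow(a@vertices) == 0L || nrow(b@vertices) == 0L)
        stop("Hausdorff distance undefined for an empty mesh")
    cppHausdorffMax(a@vertices, b@vertices)
}

#' Normalized volume variance of repeated measurements
#'
#' Sample variance (denominator n - 1) of the repeated volumes divided by
#' their mean, times 100. This is the between-repetition volume variance
#' normalized to the mean muscle (sub)volume, reported as a percentage.
#'
#' @param volumes_mm3 numeric vector of >= 2 positive volumes (mm^3).
#' @return nVV in percent.
#' @examples
#' normalizedVolumeVariance(c(90, 100, 110))  # 100
#' @export
normalizedVolumeVariance <- function(volumes_mm3) {
    v <- as.numeric(volumes_mm3)
    if (length(v) < 2L)
        stop("need at least 2 repeated volumes, got ", length(v))
    if (any(!is.finite(v)) || any(v <= 0))
        stop("all volumes must be positive and finite")
    100 * stats::var(v) / mean(v)
}

#' Coefficient of variation of repeated volumes
#'
#' Dimensionless alternative to [normalizedVolumeVariance()] (SD over mean,
#' in percent), provided because variance/mean carries units of mm^3.
#'
#' @inheritParams normalizedVolumeVariance
#' @return CV in percent.
#' @export
volumeCV <- function(volumes_mm3) {
    v <- as.numeric(volumes_mm3)
    if (length(v) < 2L || any(v <= 0))
        stop("need >= 2 positive volumes")
    100 * stats::sd(v) / mean(v)
}

#' Per-level repeatability metrics across segmentation repeats
#'
#' For each sub-volume level, compares all unordered pairs of repeats
#' (1st vs 2nd, 2nd vs 3rd, 1st vs 3rd for three repeats): Jaccard index on
#' the voxel masks, maximal Hausdorff distance on the extracted boundary
#' surfaces, and normalized volume variance on the level volumes. JI and HD
#' are averaged over the pairs; nVV is evaluated on the level volumes
#' expressed in cm^3 (variance/mean retains a volume unit, and cm^3 is the
#' conventional muscle-volume unit). A level that is empty in any repeat is
#' flagged (\code{excluded = TRUE}, metric columns NA) and reported with a
#' warning, modelling a contour the operator could not identify.
#'
#' @param repeats list of >= 2 [SubvolumeSeries-class] objects on a shared
#'   grid with matching levels.
#' @param subject_id,muscle identifiers copied into the output.
#' @return a data.frame with one row per level: \code{subject}, \code{muscle},
#'   \code{level_percent}, \code{ji_mean}, \code{hd_mean_mm},
#'   \code{nvv_percent}, \code{n_pairs}, \code{excluded}, plus list columns
#'   \code{pairwise_ji}, \code{pairwise_hd_mm}, \code{volumes_mm3}.
#' @export
compareRepeats <- function(repeats, subject_id = "s1",
                           muscle = c("gluteus_medius", "iliopsoas")) {
    muscle <- match.arg(muscle)
    if (length(repeats) < 2L)
        stop("need at least 2 repeated segmentations")
    if (!all(vapply(repeats, is, logical(1L), class2 = "SubvolumeSeries")))
        stop("repeats must be SubvolumeSeries objects")
    nl <- length(repeats[[1L]])
    lp <- repeats[[1L]]@levelPercent
    for (r in repeats)
        if (length(r) != nl || !identical(r@levelPercent, lp))
            stop("all repeats must share the same levels")
    pairs <- utils::combn(length(repeats), 2L)
    rows <- vector("list", nl)
    for (k in seq_len(nl)) {
        vols <- lapply(repeats, function(r) r[[k]])
        counts <- vapply(vols, function(v) sum(v@voxels), numeric(1L))
        if (any(counts == 0L)) {
            warning(sprintf(
                "level %d%%: empty in repeat(s) %s; flagged and excluded",
                lp[k], paste(which(counts == 0L), collapse = ", ")))
            rows[[k]] <- data.frame(
                subject = subject_id, muscle = muscle, level_percent = lp[k],
                ji_mean = NA_real_, hd_mean_mm = NA_real_,
                nvv_percent = NA_real_, n_pairs = ncol(pairs),
                excluded = TRUE)
            rows[[k]]$pairwise_ji <- list(numeric(0L))
            rows[[k]]$pairwise_hd_mm <- list(numeric(0L))
            rows[[k]]$volumes_mm3 <- list(
                counts * abs(det(vols[[1L]]@affine[1:3, 1:3])))
            next
        }
        surfs <- lapply(vols, maskToSurface)
        ji <- apply(pairs, 2L, function(p)
            jaccard(vols[[p[1L]]], vols[[p[2L]]]))
        hd <- apply(pairs, 2L, function(p)
            hausdorffMax(surfs[[p[1L]]], surfs[[p[2L]]]))
        vmm <- vapply(vols, volumeMm3, numeric(1L))
        rows[[k]] <- data.frame(
            subject = subject_id, muscle = muscle, level_percent = lp[k],
            ji_mean = mean(ji), hd_mean_mm = mean(hd),
            # nVV on volumes in cm^3, the natural muscle-volume unit:
            # variance/mean is not dimensionless, and cm^3 puts whole-muscle
            # nVV in the few-percent range
            nvv_percent = normalizedVolumeVariance(vmm / 1000),
            n_pairs = ncol(pairs), excluded = FALSE)
        rows[[k]]$pairwise_ji <- list(ji)
        rows[[k]]$pairwise_hd_mm <- list(hd)
        rows[[k]]$volumes_mm3 <- list(vmm)
    }
    do.call(rbind, rows)
}
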