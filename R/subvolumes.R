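#' Build the muscle origin-insertion axis
#'
#' The line connecting the muscle origin and insertion points defines the
#' muscle length L and the normal of all cutting planes. The axis center is
#' the scalar projection of the attachment midpoint onto the direction: the
#' sub-volume slabs grow outward from the mid-point between attachments.
#'
#' @param origin,insertion length-3 world-mm points; must be distinct
#'   (distance > 1e-6 mm).
#' @return a [MuscleAxis-class].
#' @examples
#' makeAxis(c(0, 0, 0), c(0, 0, 100))
#' @export
makeAxis <- function(origin, insertion) {
    origin <- as.numeric(origin); insertion <- as.numeric(insertion)
    L <- sqrt(sum((insertion - origin)^2))
    if (L <= 1e-6)
        stop("origin and insertion coincide (distance ", format(L), " mm)")
    d <- (insertion - origin) / L
    new("MuscleAxis", origin = origin, insertion = insertion,
        direction = d, length = L,
        center = sum(d * (origin + insertion) / 2))
}

# scalar projections of all voxel centers onto the axis direction,
# as an array matching the voxel grid; separable in i, j, k
.voxel_projections <- function(vol, axis) {
    d <- dim(vol@voxels)
    A <- vol@affine
    w <- as.numeric(axis@direction %*% A[1:3, 1:3])  # per-index-step gains
    w0 <- sum(axis@direction * A[1:3, 4L])
    pi_ <- w[1L] * (seq_len(d[1L]) - 1)
    pj <- w[2L] * (seq_len(d[2L]) - 1)
    pk <- w[3L] * (seq_len(d[3L]) - 1)
    outer(outer(pi_, pj, `+`), pk, `+`) + w0
}

#' Remove the proximal muscle end above a standardization plane
#'
#' For muscles whose proximal extremity exceeds the imaged volume (the
#' iliopsoas case), segmented volumes are standardized before sub-volume
#' analysis: a cutting plane normal to the origin-insertion line and passing
#' through \code{plane_point} (e.g. the midpoint of the left and right iliac
#' crest landmarks) removes everything on the origin (proximal) side of the
#' plane. Voxels exactly on the plane are kept.
#'
#' @param vol a [LabelVolume-class].
#' @param axis the [MuscleAxis-class]; its origin defines the proximal side.
#' @param plane_point length-3 world-mm point the plane passes through.
#' @return the standardized [LabelVolume-class] on the same grid.
#' @export
standardizeProximal <- function(vol, axis, plane_point) {
    stopifnot(is(vol, "LabelVolume"), is(axis, "MuscleAxis"))
    proj <- .voxel_projections(vol, axis)
    fg <- vol@voxels
    if (!any(fg))
        stop("cannot standardize an empty label volume")
    p_plane <- sum(axis@direction * as.numeric(plane_point))
    p_origin <- sum(axis@direction * axis@origin)
    rng <- range(proj[fg])
    # proximal = origin side; with direction pointing origin -> insertion the
    # origin has the smaller projection, so remove proj < p_plane
    proximal_is_low <- p_origin <= sum(axis@direction * axis@insertion)
    if (p_plane < rng[1L] || p_plane > rng[2L]) {
        removes_nothing <- (proximal_is_low && p_plane < rng[1L]) ||
            (!proximal_is_low && p_plane > rng[2L])
        if (removes_nothing) {
            warning("standardization plane lies proximal to the whole muscle; volume unchanged")
            return(vol)
        }
        stop("standardization plane lies distal to the whole muscle: the cut would remove all foreground (segmentation/landmark mismatch)")
    }
    keep <- if (proximal_is_low) proj >= p_plane else proj <= p_plane
    out <- fg & keep
    if (!any(out))
        stop("standardization removed all foreground (segmentation/landmark mismatch)")
    new("LabelVolume", voxels = out, affine = vol@affine)
}

#' Decompose a segmentation into nested sub-volumes along the muscle axis
#'
#' Starting from the mid-point between the muscle attachments, two parallel
#' cutting planes orthogonal to the origin-insertion line are moved outward
#' in steps of \code{step_fraction} of the muscle length L; at each step
#' only the volume between the planes is kept. Level k therefore contains
#' the voxels whose center projection p satisfies
#' \eqn{|p - c| \le k \cdot step \cdot L} (voxels exactly on a plane are
#' included), and the final level is the complete, uncut segmentation. With
#' the defaults this yields ten nested sub-volumes covering 10%, 20%, ...,
#' 100% of the muscle length.
#'
#' @param vol a nonempty [LabelVolume-class].
#' @param axis a [MuscleAxis-class].
#' @param step_fraction plane step as a fraction of L (default 0.05, i.e.
#'   5% per side per level).
#' @param n_levels number of levels (default 10).
#' @return a [SubvolumeSeries-class] with \code{n_levels} nested levels.
#' @examples
#' v <- labelVolume(array(1, c(5, 5, 50)), spacing = c(2, 2, 2))
#' ax <- makeAxis(c(4, 4, 0), c(4, 4, 99))
#' s <- cutSeries(v, ax)
#' sapply(seq_len(10), function(k) volumeMm3(s[[k]]))
#' @export
cutSeries <- function(vol, axis, step_fraction = 0.05, n_levels = 10L) {
    stopifnot(is(vol, "LabelVolume"), is(axis, "MuscleAxis"))
    n_levels <- as.integer(n_levels)
    if (n_levels < 1L) stop("n_levels must be >= 1")
    if (step_fraction <= 0) stop("step_fraction must be positive")
    if (step_fraction * n_levels > 0.5 + 1e-12)
        stop("step_fraction * n_levels must not exceed 0.5 (planes beyond the attachments)")
    fg <- vol@voxels
    if (!any(fg))
        stop("cannot cut an empty label volume")
    proj <- .voxel_projections(vol, axis)
    off <- abs(proj - axis@center)
    levels <- vector("list", n_levels)
    for (k in seq_len(n_levels - 1L)) {
        half <- k * step_fraction * axis@length
        levels[[k]] <- new("LabelVolume", voxels = fg & (off <= half),
                           affine = vol@affine)
    }
    levels[[n_levels]] <- vol   # the complete segmentation
    if (!any(levels[[1L]]@voxels))
        stop("innermost sub-volume is empty: the axis center lies outside the segmentation (axis/segmentation inconsistency)")
    # nesting is structural (off <= half is monotone in k) but asserted
    for (k in seq_len(n_levels - 1L))
        if (any(levels[[k]]@voxels & !levels[[k + 1L]]@voxels))
            stop("internal error: sub-volume nesting violated at level ", k)
    new("SubvolumeSeries", levels = levels,
        levelPercent = as.integer(round(
            seq_len(n_levels) * 2 * step_fraction * 100)),
        axis = axis)
}
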