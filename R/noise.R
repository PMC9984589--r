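#' Specify the segmentation noise model
#'
#' Describes how a repeated manual segmentation deviates from the truth:
#' slice by slice, the 2D contour is displaced inward/outward by a smooth
#' random field along the contour, with a standard deviation that grows
#' linearly from the muscle belly toward the extremities (muscle ends are
#' harder to identify on MRI than the belly), and terminal slices may be
#' missed entirely.
#'
#' @param belly_sigma_mm boundary displacement SD (mm) at the axis center.
#' @param extremity_sigma_mm displacement SD (mm) at the muscle ends; the SD
#'   at a voxel is interpolated linearly in the normalized axis coordinate
#'   |p - c| / (L / 2).
#' @param correlation_length_mm smoothness of the boundary displacement
#'   field along the contour arclength (mm); the field is a stationary
#'   Gaussian process on the contour with a squared-exponential spectrum.
#' @param end_slice_dropout_prob probability that a terminal slice's contour
#'   is missed entirely, in [0, 1].
#' @param seed integer seed; one global seed expands into per-repeat,
#'   per-slice substreams by fixed hashing, so repeats are independent and
#'   individually reproducible.
#' @return a \code{NoiseModel} list (class \code{"NoiseModel"}).
#' @seealso [simulateRepeats()]
#' @export
noiseModel <- function(belly_sigma_mm = 0.5, extremity_sigma_mm = 3,
                       correlation_length_mm = 10,
                       end_slice_dropout_prob = 0.1, seed = 1L) {
    stopifnot(belly_sigma_mm >= 0, extremity_sigma_mm >= 0,
              correlation_length_mm > 0,
              end_slice_dropout_prob >= 0, end_slice_dropout_prob <= 1)
    structure(list(belly_sigma_mm = belly_sigma_mm,
                   extremity_sigma_mm = extremity_sigma_mm,
                   correlation_length_mm = correlation_length_mm,
                   end_slice_dropout_prob = end_slice_dropout_prob,
                   seed = as.integer(seed)),
              class = "NoiseModel")
}

# smooth periodic Gaussian field on the circle, variance sigma2, angular
# correlation phi0 (rad), evaluated at angles theta; spectral synthesis
.circle_field <- function(theta, sigma2, phi0) {
    J <- max(8L, min(64L, ceiling(4 / max(phi0, 1e-3))))
    u <- exp(-0.5 * ((0:J) * phi0)^2)
    v <- sigma2 * u / sum(u)
    a <- stats::rnorm(J + 1L, sd = sqrt(v))
    b <- c(0, stats::rnorm(J, sd = sqrt(v[-1L])))
    f <- rep(a[1L], length(theta))
    for (j in seq_len(J))
        f <- f + a[j + 1L] * cos(j * theta) + b[j + 1L] * sin(j * theta)
    f
}

# dead-zone corrected signed distance (mm) of pixel centers to the contour:
# positive inside, negative outside
.signed_distance_mm <- function(slice, px) {
    din <- EBImage::distmap(slice)
    dout <- EBImage::distmap(1 - slice)
    ifelse(slice > 0, (din - 0.5) * px, -(dout - 0.5) * px)
}

#' Simulate repeated manual segmentations of a truth volume
#'
#' Each repeat perturbs the truth slice by slice: the in-slice boundary is
#' displaced inward/outward by a smooth Gaussian random field along the
#' contour whose SD interpolates from \code{belly_sigma_mm} at the axis
#' center to \code{extremity_sigma_mm} at the ends; terminal slices are
#' dropped with \code{end_slice_dropout_prob}; each repeat is reduced to its
#' largest 6-connected component so it remains a single muscle. A slice
#' whose interior vanishes under the perturbation is retained as empty and
#' reported (a missed contour). With all sigmas and the dropout probability
#' zero, every repeat is an exact copy of the truth.
#'
#' @param truth a nonempty [LabelVolume-class].
#' @param axis the [MuscleAxis-class] (for extremity weighting).
#' @param noise a [noiseModel()].
#' @param n_repeats number of repeats (>= 2; the study design uses 3).
#' @return a list of \code{n_repeats} [LabelVolume-class] objects on the
#'   truth grid.
#' @export
simulateRepeats <- function(truth, axis, noise, n_repeats = 3L) {
    stopifnot(is(truth, "LabelVolume"), is(axis, "MuscleAxis"),
              inherits(noise, "NoiseModel"))
    n_repeats <- as.integer(n_repeats)
    if (n_repeats < 2L) stop("need at least 2 repeats")
    fg <- truth@voxels
    if (!any(fg)) stop("truth volume is empty")
    if (noise$belly_sigma_mm == 0 && noise$extremity_sigma_mm == 0 &&
        noise$end_slice_dropout_prob == 0)
        return(replicate(n_repeats, truth, simplify = FALSE))

    d <- dim(fg)
    px <- mean(voxelSpacing(truth)[1:2])
    proj <- .voxel_projections(truth, axis)
    slice_has_fg <- which(apply(fg, 3L, any))
    terminal <- range(slice_has_fg)
    # mean axis coordinate of each slice's truth foreground
    slice_u <- vapply(slice_has_fg, function(k) {
        p <- proj[, , k][fg[, , k]]
        min(1, abs(mean(p) - axis@center) / (axis@length / 2))
    }, numeric(1L))
    names(slice_u) <- slice_has_fg

    out <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
        rep_vox <- fg
        dropped <- withSeed(substreamSeed(noise$seed, r, 0L),
                            stats::runif(2L) < noise$end_slice_dropout_prob)
        for (k in slice_has_fg) {
            if ((k == terminal[1L] && dropped[1L]) ||
                (k == terminal[2L] && dropped[2L])) {
                rep_vox[, , k] <- FALSE
                message(sprintf(
                    "repeat %d: terminal slice %d dropped (missed contour)",
                    r, k))
                next
            }
            u <- slice_u[[as.character(k)]]
            sigma <- noise$belly_sigma_mm +
                (noise$extremity_sigma_mm - noise$belly_sigma_mm) * u
            if (sigma == 0) next
            slice <- fg[, , k]
            sd_mm <- .signed_distance_mm(slice * 1, px)
            ij <- which(slice, arr.ind = TRUE)
            ctr <- colMeans(ij)
            rbar <- max(px, sqrt(sum(slice) * px^2 / pi))
            theta <- atan2((row(slice) - ctr[1L]) * px,
                           (col(slice) - ctr[2L]) * px)
            f <- withSeed(substreamSeed(noise$seed, r, k), {
                coefs_theta <- .circle_field(
                    as.vector(theta), sigma^2,
                    noise$correlation_length_mm / rbar)
                coefs_theta
            })
            new_slice <- matrix(as.vector(sd_mm) + f >= 0, d[1L], d[2L])
            if (!any(new_slice))
                message(sprintf(
                    "repeat %d: slice %d interior vanished under perturbation; retained empty",
                    r, k))
            rep_vox[, , k] <- new_slice
        }
        if (!any(rep_vox))
            stop("simulated repeat ", r, " is empty; noise model too severe")
        lab <- cppLabelComponents(as.vector(rep_vox), dim(rep_vox))
        ncomp <- attr(lab, "ncomp")
        if (ncomp > 1L) {
            sizes <- tabulate(lab, nbins = ncomp)
            keep <- which.max(sizes)
            rep_vox <- array(lab == keep, dim = d)
        }
        out[[r]] <- new("LabelVolume", voxels = rep_vox,
                        affine = truth@affine)
    }
    out
}
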