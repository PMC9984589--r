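#' Specify a synthetic muscle phantom
#'
#' Parameters of a ground-truth muscle label phantom emulating coronal
#' T1-weighted acquisitions (0.817 mm in-plane pixels, 4-6 mm slices,
#' following typical 1.5 T clinical protocols). Three shapes are available:
#' a straight tube, a tapered tube whose radius shrinks toward the
#' extremities, and a wrapped tube whose centerline bows laterally mid-length
#' (an iliopsoas-like muscle wrapping around the iliac crest).
#'
#' @param muscle_kind \code{"straight_tube"}, \code{"tapered_tube"} or
#'   \code{"wrapped_tube"}.
#' @param length_mm muscle length (origin to insertion), > 2 slice
#'   thicknesses.
#' @param max_radius_mm mid-muscle radius in mm.
#' @param taper radius reduction at the extremities, in [0, 1): the radius at
#'   a normalized axis position s is \code{max_radius_mm * (1 - taper *
#'   (2 s - 1)^2)}.
#' @param wrap_offset_mm lateral bow of the centerline at mid-length (mm).
#' @param pixel_mm in-plane pixel size (default 0.817).
#' @param slice_mm slice thickness (default 4).
#' @param grid_dim integer length-3 grid dimensions, or NULL to auto-size the
#'   grid to the muscle plus a 5-voxel margin. An explicit grid too small for
#'   the muscle plus margin is rejected.
#' @param seed integer seed controlling the generated atlas transform.
#' @return a \code{PhantomSpec} list (class \code{"PhantomSpec"}).
#' @seealso [makePhantom()]
#' @export
phantomSpec <- function(muscle_kind = c("straight_tube", "tapered_tube",
                                        "wrapped_tube"),
                        length_mm = 100, max_radius_mm = 15, taper = 0,
                        wrap_offset_mm = 0, pixel_mm = 0.817, slice_mm = 4,
                        grid_dim = NULL, seed = 1L) {
    muscle_kind <- match.arg(muscle_kind)
    stopifnot(length_mm > 0, max_radius_mm > 0, pixel_mm > 0, slice_mm > 0)
    if (taper < 0 || taper >= 1) stop("taper must be in [0, 1)")
    if (length_mm <= 2 * slice_mm)
        stop("length_mm must exceed 2 slice thicknesses (",
             2 * slice_mm, " mm)")
    spec <- list(muscle_kind = muscle_kind, length_mm = length_mm,
                 max_radius_mm = max_radius_mm, taper = taper,
                 wrap_offset_mm = wrap_offset_mm, pixel_mm = pixel_mm,
                 slice_mm = slice_mm, grid_dim = grid_dim,
                 seed = as.integer(seed))
    class(spec) <- "PhantomSpec"
    spec
}

# minimal grid (with a 5-voxel margin on every side) for a spec
.required_grid <- function(spec) {
    R <- spec$max_radius_mm
    wrap <- abs(spec$wrap_offset_mm)
    nx <- ceiling((2 * R + wrap) / spec$pixel_mm) + 1L + 10L
    ny <- ceiling(2 * R / spec$pixel_mm) + 1L + 10L
    n_slices <- floor((spec$length_mm - spec$slice_mm / 2) /
                          spec$slice_mm) + 1L
    nz <- n_slices + 10L
    c(nx, ny, nz)
}

#' Generate a ground-truth muscle phantom study
#'
#' Rasterizes the phantom described by a [phantomSpec()] onto an anisotropic
#' voxel grid (single 6-connected foreground component), places the muscle
#' origin and insertion on the centerline ends, derives twelve bony
#' landmarks at deterministic offsets from the muscle frame (including left
#' and right iliac-crest points used for proximal standardization), draws a
#' random but seed-determined atlas-to-subject affine, back-transforms
#' landmarks and attachments to the atlas side, and builds a synthetic bone
#' surface touching both attachments. Repeats are not simulated here; see
#' [simulateRepeats()].
#'
#' The muscle axis runs along the slice-stack normal with the origin at the
#' proximal (high-z) end; the world frame is RAS mm with the insertion at
#' the world origin.
#'
#' @param spec a [phantomSpec()].
#' @param landmark_jitter_mm SD of optional isotropic Gaussian jitter added
#'   to the subject landmarks (default 0: the true affine maps atlas
#'   landmarks onto subject landmarks exactly).
#' @return a [PhantomStudy-class] (with an empty repeat list).
#' @examples
#' st <- makePhantom(phantomSpec(length_mm = 40, max_radius_mm = 6,
#'                               pixel_mm = 2, slice_mm = 4))
#' st
#' @export
makePhantom <- function(spec, landmark_jitter_mm = 0) {
    stopifnot(inherits(spec, "PhantomSpec"))
    need <- .required_grid(spec)
    gd <- spec$grid_dim
    if (is.null(gd)) {
        gd <- need
    } else {
        gd <- as.integer(gd)
        if (length(gd) != 3L || any(gd < need))
            stop("grid too small for the muscle plus a 5-voxel margin: ",
                 "need at least (", paste(need, collapse = ", "),
                 "), got (", paste(gd, collapse = ", "), ")")
    }
    px <- spec$pixel_mm; sz <- spec$slice_mm
    L <- spec$length_mm; R <- spec$max_radius_mm
    wrap <- if (spec$muscle_kind == "wrapped_tube") spec$wrap_offset_mm else 0
    # world origin: centerline base (insertion) at (0,0,0); 5-voxel margins
    x0 <- -(R + 5 * px) - max(0, -wrap)
    y0 <- -(R + 5 * px)
    z0 <- -4.5 * sz
    affine <- diag(4)
    diag(affine)[1:3] <- c(px, px, sz)
    affine[1:3, 4L] <- c(x0, y0, z0)

    xs <- x0 + px * (seq_len(gd[1L]) - 1)
    ys <- y0 + px * (seq_len(gd[2L]) - 1)
    zs <- z0 + sz * (seq_len(gd[3L]) - 1)
    vox <- array(FALSE, gd)
    for (k in seq_len(gd[3L])) {
        z <- zs[k]
        if (z < 0 || z > L) next
        s <- z / L
        r <- switch(spec$muscle_kind,
                    straight_tube = R,
                    tapered_tube = R * (1 - spec$taper * (2 * s - 1)^2),
                    wrapped_tube = R)
        xoff <- if (spec$muscle_kind == "wrapped_tube")
            wrap * sin(pi * s) else 0
        vox[, , k] <- outer((xs - xoff)^2, ys^2, `+`) <= r^2
    }
    truth <- new("LabelVolume", voxels = vox, affine = affine)

    insertion <- c(0, 0, 0)
    origin <- c(0, 0, L)
    attachments <- landmarkSet(c("origin", "insertion"),
                               rbind(origin, insertion))
    lm_names <- c("iliac_crest_R", "iliac_crest_L", "ASIS_R", "ASIS_L",
                  "PSIS_R", "PSIS_L", "greater_trochanter_R",
                  "greater_trochanter_L", "lesser_trochanter_R",
                  "lesser_trochanter_L", "femoral_head_R", "femoral_head_L")
    lm <- rbind(c( 60,  10, 0.80 * L), c(-60,  10, 0.80 * L),
                c( 55,  40, 0.70 * L), c(-55,  40, 0.70 * L),
                c( 25, -45, 0.72 * L), c(-25, -45, 0.72 * L),
                c( 70,   0, 0.35 * L), c(-70,   0, 0.35 * L),
                c( 35, -10, 0.25 * L), c(-35, -10, 0.25 * L),
                c( 45,   5, 0.50 * L), c(-45,   5, 0.50 * L))
    landmarks <- landmarkSet(lm_names, lm)

    trueAffine <- withSeed(substreamSeed(spec$seed, 1L), {
        ang <- stats::runif(3L, -0.15, 0.15)
        Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
                    c(0, sin(ang[1]), cos(ang[1])))
        Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
                    c(-sin(ang[2]), 0, cos(ang[2])))
        Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                    c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
        S <- diag(stats::runif(3L, 0.9, 1.1))
        shear <- diag(3); shear[1L, 2L] <- stats::runif(1L, -0.05, 0.05)
        affineTransform(Rz %*% Ry %*% Rx %*% S %*% shear,
                        stats::runif(3L, -20, 20))
    })
    inv <- invertTransform(trueAffine)
    atlasLandmarks <- applyTransform(inv, landmarks)
    atlasAttachments <- applyTransform(inv, attachments)
    if (landmark_jitter_mm > 0) {
        landmarks <- withSeed(substreamSeed(spec$seed, 2L), landmarkSet(
            landmarks@names,
            landmarks@coords + matrix(
                stats::rnorm(3L * length(landmarks@names),
                             sd = landmark_jitter_mm), ncol = 3L)))
    }
    bone <- .merge_meshes(
        .box_mesh(c(-25, -25, L), c(25, 25, L + 30)),      # pelvic block
        .box_mesh(c(-25, -25, -30), c(25, 25, 0)))         # femoral block
    spec$grid_dim <- gd
    new("PhantomStudy", truth = truth, repeats = list(),
        landmarks = landmarks, atlasLandmarks = atlasLandmarks,
        atlasAttachments = atlasAttachments, trueAffine = trueAffine,
        boneSurface = bone, spec = unclass(spec))
}

#' @describeIn makePhantom the subject attachment landmark set (origin and
#'   insertion on the centerline ends) implied by a study's spec.
#' @param study a [PhantomStudy-class].
#' @export
phantomAttachments <- function(study) {
    applyTransform(study@trueAffine, study@atlasAttachments)
}
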