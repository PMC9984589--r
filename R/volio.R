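#' Construct a LabelVolume
#'
#' @param voxels a 3D array; values are thresholded at > 0.5 to foreground,
#'   so logical, 0/1 integer and float masks are all accepted.
#' @param affine 4x4 voxel-index (0-based, voxel centers) to world-mm matrix.
#'   Alternatively \code{NULL} with \code{spacing} given, in which case an
#'   axis-aligned affine with zero origin is built.
#' @param spacing voxel spacing in mm, used only when \code{affine} is NULL.
#' @return a [LabelVolume-class].
#' @examples
#' v <- labelVolume(array(1, c(4, 4, 4)), spacing = c(0.8, 0.8, 4))
#' volumeMm3(v)
#' @export
labelVolume <- function(voxels, affine = NULL, spacing = c(1, 1, 1)) {
    if (length(dim(voxels)) != 3L)
        stop("voxels must be a 3D array, got shape (",
             paste(dim(voxels), collapse = ", "), ")")
    if (is.null(affine)) {
        affine <- diag(4)
        diag(affine)[1:3] <- spacing
    }
    storage.mode(affine) <- "double"
    v <- array(as.vector(voxels) > 0.5, dim = dim(voxels))
    new("LabelVolume", voxels = v, affine = affine)
}

#' Read / write a binary label volume as NIfTI
#'
#' Masks are written as uint8 0/1 with the affine stored in the sform
#' (code 2). On read, any value > 0.5 is foreground, tolerating float masks
#' from other tools. World coordinates follow the NIfTI convention: the
#' affine maps 0-based voxel indices (voxel centers) to RAS mm.
#'
#' @param path a .nii or .nii.gz file.
#' @return a [LabelVolume-class].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeLabelVolume(labelVolume(array(1, c(3, 3, 3))), f)
#' readLabelVolume(f)
#' @export
readLabelVolume <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    im <- RNifti::readNifti(path)
    d <- dim(im)
    if (length(d) != 3L)
        stop("expected a 3D label volume, got shape (",
             paste(d, collapse = ", "), ")")
    im2 <- im
    aff <- RNifti::xform(im, useQuaternionFirst = FALSE)
    aff <- matrix(as.numeric(aff), 4L, 4L)
    labelVolume(array(as.numeric(im2), dim = dim(im2)), affine = aff)
}

#' @rdname readLabelVolume
#' @param vol a [LabelVolume-class].
#' @export
writeLabelVolume <- function(vol, path) {
    stopifnot(is(vol, "LabelVolume"))
    im <- RNifti::asNifti(array(as.integer(vol@voxels), dim = dim(vol@voxels)),
                          datatype = "uint8")
    im <- RNifti::`sform<-`(im, structure(vol@affine, code = 2L))
    RNifti::writeNifti(im, path, datatype = "uint8")
    invisible(path)
}

#' Physical volume of a label mask
#'
#' Foreground voxel count times the voxel volume
#' \eqn{|\det A_{3\times3}|}; invariant under rigid re-orientation of the
#' affine. The per-repetition volumes feed the normalized volume variance.
#'
#' @param vol a [LabelVolume-class].
#' @return volume in mm^3 (0 for an empty mask).
#' @examples
#' v <- labelVolume(array(1, c(10, 10, 1)), spacing = c(0.8, 0.8, 5))
#' volumeMm3(v)  # 100 * 0.8 * 0.8 * 5 = 320
#' @export
volumeMm3 <- function(vol) {
    stopifnot(is(vol, "LabelVolume"))
    sum(vol@voxels) * abs(det(vol@affine[1:3, 1:3]))
}

#' Construct a SurfaceMesh
#'
#' @param vertices n x 3 numeric matrix (world mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @return a [SurfaceMesh-class].
#' @export
surfaceMesh <- function(vertices, faces) {
    vertices <- matrix(as.numeric(vertices), ncol = 3L)
    faces <- matrix(as.integer(faces), ncol = 3L)
    new("SurfaceMesh", vertices = vertices, faces = faces)
}

#' Construct a LandmarkSet
#'
#' @param names character vector of unique names.
#' @param coords n x 3 numeric matrix, world mm.
#' @return a [LandmarkSet-class].
#' @export
landmarkSet <- function(names, coords) {
    coords <- matrix(as.numeric(coords), ncol = 3L)
    new("LandmarkSet", names = as.character(names), coords = coords)
}

#' Read / write landmark files
#'
#' Plain CSV with header \code{name,x,y,z}, coordinates in world mm. Written
#' with 12 significant digits so round trips are exact to formatting
#' precision. Row order is preserved.
#'
#' @param path a CSV file path.
#' @return a [LandmarkSet-class].
#' @export
readLandmarks <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "character"))
    if (!identical(names(df), c("name", "x", "y", "z")))
        stop("landmark file must have header name,x,y,z; got: ",
             paste(names(df), collapse = ","))
    if (nrow(df) == 0L) {
        warning("landmark file ", path, " contains no landmarks")
        return(landmarkSet(character(0L), matrix(numeric(0L), 0L, 3L)))
    }
    co <- suppressWarnings(cbind(as.numeric(df$x), as.numeric(df$y),
                                 as.numeric(df$z)))
    bad <- which(rowSums(is.na(co)) > 0L)
    if (length(bad) > 0L)
        stop("non-numeric coordinate in landmark row ", bad[1L],
             " (", df$name[bad[1L]], ")")
    if (anyDuplicated(df$name))
        stop("duplicate landmark name: ", df$name[anyDuplicated(df$name)])
    landmarkSet(df$name, co)
}

#' @rdname readLandmarks
#' @param set a [LandmarkSet-class].
#' @export
writeLandmarks <- function(set, path) {
    stopifnot(is(set, "LandmarkSet"))
    df <- data.frame(name = set@names,
                     x = formatC(set@coords[, 1L], digits = 12,
                                 format = "g"),
                     y = formatC(set@coords[, 2L], digits = 12,
                                 format = "g"),
                     z = formatC(set@coords[, 3L], digits = 12,
                                 format = "g"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Extract a closed boundary surface from a label volume
#'
#' Builds the closed triangulated boundary surface of the foreground at the
#' 0.5 iso-level of the voxel indicator: every face between a foreground and
#' a background (or out-of-grid) voxel contributes a quad at the half-voxel
#' boundary, split into two consistently oriented triangles and mapped to
#' world mm through the volume affine. The enclosed mesh volume therefore
#' equals the voxel-count volume exactly; surfaces feed the maximal
#' Hausdorff distance.
#'
#' @param vol a nonempty [LabelVolume-class].
#' @return a [SurfaceMesh-class] in world mm.
#' @examples
#' v <- labelVolume(array(1, c(2, 2, 2)))
#' meshVolume(maskToSurface(v))  # 8 mm^3
#' @export
maskToSurface <- function(vol) {
    stopifnot(is(vol, "LabelVolume"))
    fg <- vol@voxels
    if (!any(fg))
        stop("cannot extract a surface from an empty label volume")
    d <- dim(fg)
    pad <- array(FALSE, d + 2L)
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- fg

    quads <- vector("list", 6L)
    qn <- 0L
    # offsets of the 4 quad corners (in doubled half-step units relative to
    # the voxel center at (0,0,0)), ordered counter-clockwise as seen from
    # outside (the +dir side for positive faces)
    corner_tab <- list(
        `+1` = rbind(c(1, -1, -1), c(1, 1, -1), c(1, 1, 1), c(1, -1, 1)),
        `-1` = rbind(c(-1, -1, -1), c(-1, -1, 1), c(-1, 1, 1), c(-1, 1, -1)),
        `+2` = rbind(c(-1, 1, -1), c(-1, 1, 1), c(1, 1, 1), c(1, 1, -1)),
        `-2` = rbind(c(-1, -1, -1), c(1, -1, -1), c(1, -1, 1), c(-1, -1, 1)),
        `+3` = rbind(c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1)),
        `-3` = rbind(c(-1, -1, -1), c(-1, 1, -1), c(1, 1, -1), c(1, -1, -1)))
    shift_tab <- list(`+1` = c(1, 0, 0), `-1` = c(-1, 0, 0),
                      `+2` = c(0, 1, 0), `-2` = c(0, -1, 0),
                      `+3` = c(0, 0, 1), `-3` = c(0, 0, -1))

    centers <- NULL   # 2x voxel index of each boundary-face owner
    owners <- NULL
    kinds <- character(0L)
    for (kind in names(shift_tab)) {
        s <- shift_tab[[kind]]
        nb <- pad[(2:(d[1] + 1L)) + s[1L],
                  (2:(d[2] + 1L)) + s[2L],
                  (2:(d[3] + 1L)) + s[3L]]
        hit <- which(fg & !nb, arr.ind = TRUE)
        if (nrow(hit) == 0L) next
        owners <- rbind(owners, hit)
        kinds <- c(kinds, rep(kind, nrow(hit)))
    }

    n_quads <- nrow(owners)
    # build 4 corner coordinate rows per quad in doubled-index space
    corn <- matrix(0, n_quads * 4L, 3L)
    for (kind in unique(kinds)) {
        idx <- which(kinds == kind)
        ct <- corner_tab[[kind]]
        base2 <- 2L * (owners[idx, , drop = FALSE] - 1L)  # 0-based doubled
        for (cc in 1:4) {
            rows <- (idx - 1L) * 4L + cc
            corn[rows, ] <- sweep(base2, 2L, ct[cc, ], `+`)
        }
    }
    # deduplicate corners; doubled indices are integers in [-1, 2*d-1]
    key <- (corn[, 1L] + 2) +
        (corn[, 2L] + 2) * (2 * d[1L] + 4) +
        (corn[, 3L] + 2) * (2 * d[1L] + 4) * (2 * d[2L] + 4)
    uk <- unique(key)
    vid <- match(key, uk)
    first <- match(uk, key)
    vert_idx <- corn[first, , drop = FALSE] / 2  # back to voxel-index units
    verts <- cbind(vert_idx, 1) %*% t(vol@affine)
    verts <- verts[, 1:3, drop = FALSE]

    q <- matrix(vid, ncol = 4L, byrow = TRUE)
    faces <- rbind(q[, c(1L, 2L, 3L), drop = FALSE],
                   q[, c(1L, 3L, 4L), drop = FALSE])
    surfaceMesh(verts, faces)
}

#' Enclosed volume of a closed surface mesh
#'
#' Signed-tetrahedron (divergence theorem) volume; the absolute value is
#' returned so the result does not depend on global orientation.
#'
#' @param mesh a closed [SurfaceMesh-class].
#' @return enclosed volume in mm^3.
#' @export
meshVolume <- function(mesh) {
    stopifnot(is(mesh, "SurfaceMesh"))
    v <- mesh@vertices
    f <- mesh@faces
    a <- v[f[, 1L], , drop = FALSE]
    b <- v[f[, 2L], , drop = FALSE]
    c_ <- v[f[, 3L], , drop = FALSE]
    det3 <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
        a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
        a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
    abs(sum(det3)) / 6
}

#' Read / write a surface mesh as ASCII STL
#'
#' Minimal STL support for bone surfaces: facet normals are recomputed from
#' the vertex winding on write and ignored on read; identical vertices are
#' merged on read.
#'
#' @param path an .stl file path.
#' @return a [SurfaceMesh-class].
#' @export
readSTL <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    lines <- readLines(path)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
        stop("malformed STL file: ", path)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
        as.numeric(p[2:4])))
    key <- apply(nums, 1L, function(r) paste(format(r, digits = 12),
                                             collapse = "|"))
    uk <- unique(key)
    vid <- match(key, uk)
    verts <- nums[match(uk, key), , drop = FALSE]
    faces <- matrix(vid, ncol = 3L, byrow = TRUE)
    surfaceMesh(verts, faces)
}

#' @rdname readSTL
#' @param mesh a [SurfaceMesh-class].
#' @param name solid name written to the file header.
#' @export
writeSTL <- function(mesh, path, name = "surface") {
    stopifnot(is(mesh, "SurfaceMesh"))
    v <- mesh@vertices
    f <- mesh@faces
    ab <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
    ac <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
    nrm <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
                 ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
                 ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
    nrm <- nrm / sqrt(rowSums(nrm^2))
    fmt <- function(m) apply(m, 1L, function(r)
        paste(formatC(r, digits = 9, format = "g"), collapse = " "))
    out <- c(paste("solid", name),
             as.vector(rbind(paste("facet normal", fmt(nrm)),
                             "  outer loop",
                             paste("    vertex", fmt(v[f[, 1L], , drop = FALSE])),
                             paste("    vertex", fmt(v[f[, 2L], , drop = FALSE])),
                             paste("    vertex", fmt(v[f[, 3L], , drop = FALSE])),
                             "  endloop",
                             "endfacet")),
             paste("endsolid", name))
    writeLines(out, path)
    invisible(path)
}
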