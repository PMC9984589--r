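#' @useDynLib repseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' LabelVolume: a binary segmentation mask with world geometry
#'
#' The unit of segmentation: a 3D logical voxel array together with a 4x4
#' affine mapping 0-based voxel indices (voxel centers) to world coordinates
#' in millimetres (RAS). Stacked slice-by-slice 2D masks from manual
#' segmentation are represented this way once loaded from NIfTI.
#'
#' @slot voxels logical 3D array; \code{TRUE} marks foreground.
#' @slot affine numeric 4x4 matrix; last row \code{(0,0,0,1)}; the upper-left
#'   3x3 block must be invertible.
#'
#' @seealso [labelVolume()], [readLabelVolume()], [volumeMm3()],
#'   [maskToSurface()]
#' @export
setClass("LabelVolume",
         representation(voxels = "array", affine = "matrix"))

setValidity("LabelVolume", function(object) {
    v <- object@voxels
    a <- object@affine
    if (!is.logical(v) || length(dim(v)) != 3L)
        return("voxels must be a 3D logical array")
    if (anyNA(v))
        return("voxels must not contain NA")
    if (!is.numeric(a) || !all(dim(a) == c(4L, 4L)) || anyNA(a) ||
        any(!is.finite(a)))
        return("affine must be a finite numeric 4x4 matrix")
    if (!isTRUE(all.equal(a[4L, ], c(0, 0, 0, 1), tolerance = 1e-9)))
        return("last affine row must be (0, 0, 0, 1)")
    if (abs(det(a[1:3, 1:3])) <= 1e-12)
        return("affine 3x3 block is singular")
    TRUE
})

#' SurfaceMesh: a triangulated surface in world millimetres
#'
#' @slot vertices numeric n x 3 matrix of world-mm points.
#' @slot faces integer m x 3 matrix of 1-based vertex indices; triangles are
#'   consistently oriented (outward normals for closed surfaces).
#'
#' @seealso [surfaceMesh()], [maskToSurface()], [meshVolume()], [readSTL()]
#' @export
setClass("SurfaceMesh",
         representation(vertices = "matrix", faces = "matrix"))

setValidity("SurfaceMesh", function(object) {
    v <- object@vertices
    f <- object@faces
    if (!is.numeric(v) || ncol(v) != 3L || any(!is.finite(v)))
        return("vertices must be a finite numeric n x 3 matrix")
    if (!is.numeric(f) || ncol(f) != 3L || nrow(f) < 1L)
        return("faces must be an m x 3 index matrix with m >= 1")
    if (any(f != round(f)) || any(f < 1L) || any(f > nrow(v)))
        return("face indices must be integers in 1..nrow(vertices)")
    ab <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
    ac <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
    cr <- cbind(ab[, 2L] * ac[, 3L] - ab[, 3L] * ac[, 2L],
                ab[, 3L] * ac[, 1L] - ab[, 1L] * ac[, 3L],
                ab[, 1L] * ac[, 2L] - ab[, 2L] * ac[, 1L])
    if (any(rowSums(cr^2) <= 1e-24))
        return("mesh contains degenerate (zero-area) triangles")
    TRUE
})

#' LandmarkSet: named 3D points in world millimetres
#'
#' Ordered, uniquely named points, e.g. the twelve bony landmarks identified
#' by virtual palpation, or atlas muscle origin/insertion points.
#'
#' @slot names character vector of unique landmark names.
#' @slot coords numeric n x 3 matrix of world-mm coordinates.
#'
#' @seealso [landmarkSet()], [readLandmarks()], [fitAffine()]
#' @export
setClass("LandmarkSet",
         representation(names = "character", coords = "matrix"))

setValidity("LandmarkSet", function(object) {
    n <- object@names
    p <- object@coords
    if (!is.numeric(p) || ncol(p) != 3L)
        return("coords must be an n x 3 numeric matrix")
    if (length(n) != nrow(p))
        return("names and coords disagree in length")
    if (anyDuplicated(n))
        return(paste0("duplicate landmark name: ",
                      n[anyDuplicated(n)]))
    if (length(n) > 0L && any(!is.finite(p)))
        return("landmark coordinates must be finite")
    TRUE
})

#' AffineTransform: a 12-DOF world-space affine map
#'
#' Maps a point \eqn{p} to \eqn{A p + t}. Fitted from corresponding landmark
#' pairs by SVD least squares ([fitAffine()]) and used to morph atlas muscle
#' attachment points onto a subject.
#'
#' @slot matrix numeric 3x3 matrix \eqn{A}, invertible.
#' @slot translation numeric length-3 vector \eqn{t} in mm.
#'
#' @export
setClass("AffineTransform",
         representation(matrix = "matrix", translation = "numeric"))

setValidity("AffineTransform", function(object) {
    A <- object@matrix
    t <- object@translation
    if (!is.numeric(A) || !all(dim(A) == c(3L, 3L)) || any(!is.finite(A)))
        return("matrix must be a finite 3x3 numeric matrix")
    if (length(t) != 3L || any(!is.finite(t)))
        return("translation must be a finite length-3 vector")
    if (abs(det(A)) <= 1e-12)
        return("matrix is numerically singular (|det| <= 1e-12)")
    TRUE
})

#' MuscleAxis: the origin-insertion line of action
#'
#' The line connecting the muscle origin and insertion attachment points.
#' Its direction and length define the cutting planes of the sub-volume
#' decomposition; \code{center} is the scalar projection of the attachment
#' midpoint onto the direction.
#'
#' @slot origin,insertion numeric length-3 world-mm points.
#' @slot direction unit vector from origin to insertion.
#' @slot length muscle length L in mm (distance origin to insertion).
#' @slot center scalar projection of the midpoint onto \code{direction}.
#'
#' @seealso [makeAxis()], [cutSeries()], [standardizeProximal()]
#' @export
setClass("MuscleAxis",
         representation(origin = "numeric", insertion = "numeric",
                        direction = "numeric", length = "numeric",
                        center = "numeric"))

setValidity("MuscleAxis", function(object) {
    if (length(object@origin) != 3L || length(object@insertion) != 3L)
        return("origin and insertion must be length-3")
    if (object@length <= 0)
        return("length must be positive")
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-12)
        return("direction must be a unit vector")
    TRUE
})

#' SubvolumeSeries: the nested sub-volumes of one segmentation
#'
#' For one segmentation repeat, the ten nested sub-volumes obtained by moving
#' two parallel cutting planes, orthogonal to the muscle axis, outward from
#' the axis center in 5% steps of the muscle length. Level \eqn{k} keeps the
#' slab within \eqn{\pm 5k\%} of L; the last level is the complete
#' segmentation.
#'
#' @slot levels list of [LabelVolume-class] objects, one per level, on a
#'   shared voxel grid, nested (each level a subset of the next).
#' @slot levelPercent integer vector of level labels (10, 20, ..., 100).
#' @slot axis the [MuscleAxis-class] used for cutting.
#'
#' @seealso [cutSeries()]
#' @export
setClass("SubvolumeSeries",
         representation(levels = "list", levelPercent = "integer",
                        axis = "MuscleAxis"))

setValidity("SubvolumeSeries", function(object) {
    ls <- object@levels
    if (length(ls) != length(object@levelPercent))
        return("levels and levelPercent disagree in length")
    if (!all(vapply(ls, is, logical(1L), class2 = "LabelVolume")))
        return("all levels must be LabelVolume objects")
    d0 <- dim(ls[[1L]]@voxels)
    a0 <- ls[[1L]]@affine
    for (v in ls) {
        if (!identical(dim(v@voxels), d0))
            return("levels must share one voxel grid")
        if (max(abs(v@affine - a0)) > 1e-6)
            return("levels must share one affine")
    }
    TRUE
})

#' PhantomStudy: a synthetic subject bundle
#'
#' Everything the pipeline needs for one synthetic subject: the ground-truth
#' label volume, simulated repeated segmentations, subject bony landmarks,
#' the atlas landmark and attachment sets, the true atlas-to-subject affine,
#' and a synthetic bone surface for attachment snapping.
#'
#' @slot truth ground-truth [LabelVolume-class].
#' @slot repeats list of [LabelVolume-class] simulated re-segmentations, all
#'   on the truth grid.
#' @slot landmarks subject [LandmarkSet-class] (12 bony landmarks).
#' @slot atlasLandmarks,atlasAttachments atlas-side [LandmarkSet-class]s;
#'   applying \code{trueAffine} to them reproduces the subject geometry.
#' @slot trueAffine the generating [AffineTransform-class].
#' @slot boneSurface synthetic bone [SurfaceMesh-class].
#' @slot spec list; the generating phantom specification (see
#'   [phantomSpec()]).
#'
#' @seealso [makePhantom()], [simulateRepeats()], [writeStudy()]
#' @export
setClass("PhantomStudy",
         representation(truth = "LabelVolume", repeats = "list",
                        landmarks = "LandmarkSet",
                        atlasLandmarks = "LandmarkSet",
                        atlasAttachments = "LandmarkSet",
                        trueAffine = "AffineTransform",
                        boneSurface = "SurfaceMesh",
                        spec = "list"))

setValidity("PhantomStudy", function(object) {
    d0 <- dim(object@truth@voxels)
    a0 <- object@truth@affine
    for (r in object@repeats) {
        if (!is(r, "LabelVolume"))
            return("repeats must be LabelVolume objects")
        if (!identical(dim(r@voxels), d0) || max(abs(r@affine - a0)) > 1e-9)
            return("repeats must share the truth grid and affine")
    }
    TRUE
})
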