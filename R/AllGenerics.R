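#' @describeIn LabelVolume-class foreground voxel array accessor.
#' @param object,x an object of the documented class.
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @describeIn LabelVolume-class 4x4 voxel-index-to-world-mm affine accessor.
#' @export
setGeneric("worldAffine", function(object) standardGeneric("worldAffine"))

#' @describeIn LabelVolume-class voxel spacing (mm) along the three axes,
#'   i.e. the column norms of the affine 3x3 block.
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @describeIn SurfaceMesh-class vertex matrix accessor.
#' @export
setGeneric("meshVertices", function(object) standardGeneric("meshVertices"))

#' @describeIn SurfaceMesh-class face index matrix accessor.
#' @export
setGeneric("meshFaces", function(object) standardGeneric("meshFaces"))

#' @describeIn LandmarkSet-class landmark name accessor.
#' @export
setGeneric("landmarkNames", function(object) standardGeneric("landmarkNames"))

#' @describeIn LandmarkSet-class coordinate matrix accessor (rownames are the
#'   landmark names).
#' @export
setGeneric("landmarkCoords",
           function(object) standardGeneric("landmarkCoords"))

#' Transform points or landmark sets through an affine map
#'
#' Maps each point p to A p + t. Landmark names are preserved.
#'
#' @param transform an [AffineTransform-class].
#' @param points a [LandmarkSet-class] or an n x 3 numeric matrix.
#' @return an object of the same kind as \code{points}.
#' @examples
#' tr <- affineTransform(diag(3), c(1, 2, 3))
#' applyTransform(tr, matrix(0, 1, 3))
#' @export
setGeneric("applyTransform",
           function(transform, points) standardGeneric("applyTransform"))

setMethod("voxels", "LabelVolume", function(object) object@voxels)
setMethod("worldAffine", "LabelVolume", function(object) object@affine)
setMethod("voxelSpacing", "LabelVolume", function(object)
    sqrt(colSums(object@affine[1:3, 1:3]^2)))
setMethod("meshVertices", "SurfaceMesh", function(object) object@vertices)
setMethod("meshFaces", "SurfaceMesh", function(object) object@faces)
setMethod("landmarkNames", "LandmarkSet", function(object) object@names)
setMethod("landmarkCoords", "LandmarkSet", function(object) {
    p <- object@coords
    rownames(p) <- object@names
    p
})

setMethod("show", "LabelVolume", function(object) {
    d <- dim(object@voxels)
    sp <- voxelSpacing(object)
    cat(sprintf("LabelVolume %d x %d x %d voxels, spacing %.3f x %.3f x %.3f mm\n",
                d[1], d[2], d[3], sp[1], sp[2], sp[3]))
    cat(sprintf("  foreground: %d voxels (%.1f mm^3)\n",
                sum(object@voxels), volumeMm3(object)))
})

setMethod("show", "SurfaceMesh", function(object) {
    cat(sprintf("SurfaceMesh: %d vertices, %d triangles\n",
                nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "LandmarkSet", function(object) {
    cat(sprintf("LandmarkSet with %d landmarks\n", length(object@names)))
    if (length(object@names) > 0L)
        print(utils::head(landmarkCoords(object), 12L))
})

setMethod("show", "AffineTransform", function(object) {
    cat("AffineTransform (p -> A p + t)\n A =\n")
    print(object@matrix)
    cat(" t =", format(object@translation), "\n")
})

setMethod("show", "MuscleAxis", function(object) {
    cat(sprintf("MuscleAxis: L = %.2f mm, direction (%.3f, %.3f, %.3f)\n",
                object@length, object@direction[1], object@direction[2],
                object@direction[3]))
})

setMethod("show", "SubvolumeSeries", function(object) {
    cat(sprintf("SubvolumeSeries with %d levels (%s%%)\n",
                length(object@levels),
                paste(object@levelPercent, collapse = ", ")))
})

setMethod("show", "PhantomStudy", function(object) {
    cat(sprintf("PhantomStudy: %s phantom, %d repeats, %d landmarks\n",
                if (is.null(object@spec$muscle_kind)) "?" else
                    object@spec$muscle_kind,
                length(object@repeats), length(object@landmarks@names)))
})

#' @describeIn SubvolumeSeries-class number of levels.
#' @export
setMethod("length", "SubvolumeSeries", function(x) length(x@levels))

#' @describeIn SubvolumeSeries-class extract the LabelVolume of level i
#'   (1-based level index, not percent).
#' @param i level index.
#' @export
setMethod("[[", "SubvolumeSeries", function(x, i) x@levels[[i]])

#' @describeIn LandmarkSet-class number of landmarks.
#' @export
setMethod("length", "LandmarkSet", function(x) length(x@names))
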