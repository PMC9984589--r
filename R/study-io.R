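#' Write / read a phantom study bundle
#'
#' Serializes a [PhantomStudy-class] into a directory: NIfTI masks
#' (truth and repeats), landmark CSVs, an ASCII STL bone surface, and a JSON
#' manifest recording file paths, the generating spec (including its seed)
#' and the true atlas-to-subject affine, so the study can be reconstructed
#' losslessly or regenerated from the recorded spec.
#'
#' @param study a [PhantomStudy-class].
#' @param directory output directory; must be empty (or absent) unless
#'   \code{overwrite = TRUE}.
#' @param overwrite allow writing into a non-empty directory.
#' @return the manifest file path, invisibly.
#' @seealso [readStudy()]
#' @export
writeStudy <- function(study, directory, overwrite = FALSE) {
    stopifnot(is(study, "PhantomStudy"))
    if (dir.exists(directory) &&
        length(list.files(directory, all.files = TRUE, no.. = TRUE)) > 0L &&
        !overwrite)
        stop("directory ", directory,
             " is not empty; set overwrite = TRUE to write anyway")
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(directory))
        stop("cannot create directory ", directory)
    wpath <- function(f) file.path(directory, f)
    files <- list(truth = "truth.nii.gz",
                  repeats = sprintf("repeat_%02d.nii.gz",
                                    seq_along(study@repeats)),
                  landmarks = "landmarks.csv",
                  atlas_landmarks = "atlas_landmarks.csv",
                  atlas_attachments = "atlas_attachments.csv",
                  bone_surface = "bone_surface.stl")
    ok <- tryCatch({
        writeLabelVolume(study@truth, wpath(files$truth))
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
        stop("cannot write into ", directory, ": ", conditionMessage(ok))
    for (i in seq_along(study@repeats))
        writeLabelVolume(study@repeats[[i]], wpath(files$repeats[i]))
    writeLandmarks(study@landmarks, wpath(files$landmarks))
    writeLandmarks(study@atlasLandmarks, wpath(files$atlas_landmarks))
    writeLandmarks(study@atlasAttachments, wpath(files$atlas_attachments))
    writeSTL(study@boneSurface, wpath(files$bone_surface), name = "bone")
    manifest <- list(format = "repseg-study/1",
                     files = files,
                     spec = study@spec,
                     true_affine = list(
                         matrix = as.numeric(t(study@trueAffine@matrix)),
                         translation = study@trueAffine@translation))
    jsonlite::write_json(manifest, wpath("manifest.json"),
                         auto_unbox = TRUE, digits = I(17), null = "null",
                         pretty = TRUE)
    invisible(wpath("manifest.json"))
}

#' @rdname writeStudy
#' @param path a study directory or its \code{manifest.json}.
#' @return \code{readStudy} returns the reconstructed [PhantomStudy-class].
#' @export
readStudy <- function(path) {
    manifest_path <- if (dir.exists(path))
        file.path(path, "manifest.json") else path
    if (!file.exists(manifest_path))
        stop("no manifest found at ", manifest_path)
    directory <- dirname(manifest_path)
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (!identical(man$format, "repseg-study/1"))
        stop("unrecognized study manifest format: ", man$format)
    rpath <- function(f) file.path(directory, f)
    spec <- man$spec
    spec$grid_dim <- as.integer(spec$grid_dim)
    new("PhantomStudy",
        truth = readLabelVolume(rpath(man$files$truth)),
        repeats = lapply(man$files$repeats,
                         function(f) readLabelVolume(rpath(f))),
        landmarks = readLandmarks(rpath(man$files$landmarks)),
        atlasLandmarks = readLandmarks(rpath(man$files$atlas_landmarks)),
        atlasAttachments = readLandmarks(rpath(man$files$atlas_attachments)),
        trueAffine = affineTransform(
            matrix(as.numeric(man$true_affine$matrix), 3L, 3L, byrow = TRUE),
            as.numeric(man$true_affine$translation)),
        boneSurface = readSTL(rpath(man$files$bone_surface)),
        spec = spec)
}
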