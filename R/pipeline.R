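#' Configure an end-to-end repeatability study
#'
#' Collects everything [runStudy()] needs: either synthetic mode (phantoms
#' generated per muscle) or files mode (existing study directories written
#' by [writeStudy()]). Defaults mirror the analysis design: three repeats,
#' ten nested sub-volume levels in 5% steps, alpha 0.05, proximal
#' standardization for the iliopsoas only.
#'
#' @param mode \code{"synthetic"} or \code{"files"}.
#' @param n_subjects number of synthetic subjects per muscle.
#' @param muscles muscles to analyse; the iliopsoas is modelled as a wrapped
#'   tube with proximal standardization, the gluteus medius as a tapered
#'   tube without.
#' @param n_repeats repeated segmentations per subject (default 3).
#' @param noise a [noiseModel()] (its seed is re-derived per subject from
#'   \code{seed}).
#' @param step_fraction,n_levels sub-volume cutting parameters; their
#'   product must not exceed 0.5.
#' @param alpha significance level of the statistical layer.
#' @param seed global integer seed.
#' @param out_dir output directory for the report bundle.
#' @param landmark_jitter_mm optional landmark jitter SD (default 0).
#' @param max_snap_mm attachment snap threshold passed to [snapToSurface()].
#' @param study_dirs in files mode, a list of study directories (named by
#'   muscle) to load instead of generating phantoms.
#' @param overwrite allow writing into a non-empty \code{out_dir}.
#' @return a \code{StudyConfig} list.
#' @export
studyConfig <- function(mode = c("synthetic", "files"),
                        n_subjects = 20L,
                        muscles = c("gluteus_medius", "iliopsoas"),
                        n_repeats = 3L,
                        noise = noiseModel(),
                        step_fraction = 0.05, n_levels = 10L,
                        alpha = 0.05, seed = 1L,
                        out_dir = tempfile("repseg_study_"),
                        landmark_jitter_mm = 0, max_snap_mm = 15,
                        study_dirs = NULL, overwrite = FALSE) {
    mode <- match.arg(mode)
    muscles <- match.arg(muscles, several.ok = TRUE)
    if (step_fraction * n_levels > 0.5 + 1e-12)
        stop("step_fraction * n_levels must not exceed 0.5")
    if (mode == "files" && is.null(study_dirs))
        stop("files mode needs study_dirs")
    structure(list(mode = mode, n_subjects = as.integer(n_subjects),
                   muscles = muscles, n_repeats = as.integer(n_repeats),
                   noise = noise, step_fraction = step_fraction,
                   n_levels = as.integer(n_levels), alpha = alpha,
                   seed = as.integer(seed), out_dir = out_dir,
                   landmark_jitter_mm = landmark_jitter_mm,
                   max_snap_mm = max_snap_mm, study_dirs = study_dirs,
                   overwrite = overwrite),
              class = "StudyConfig")
}

#' Read a StudyConfig from a YAML file
#'
#' Scalar fields map directly onto [studyConfig()] arguments; the noise
#' block maps onto [noiseModel()].
#'
#' @param path a YAML file.
#' @return a \code{StudyConfig}.
#' @export
readStudyConfig <- function(path) {
    y <- yaml::read_yaml(path)
    noise <- if (is.null(y$noise)) noiseModel() else
        do.call(noiseModel, y$noise)
    y$noise <- NULL
    do.call(studyConfig, c(y, list(noise = noise)))
}

# phantom spec for one synthetic subject of one muscle; deterministic size
# variation across subjects
.subject_spec <- function(muscle, subject, seed) {
    s <- substreamSeed(seed, match(muscle, c("gluteus_medius", "iliopsoas")),
                       subject)
    u <- withSeed(s, stats::runif(2L))
    if (muscle == "gluteus_medius") {
        phantomSpec("tapered_tube",
                    length_mm = 90 * (0.9 + 0.2 * u[1L]),
                    max_radius_mm = 16 * (0.9 + 0.2 * u[2L]),
                    taper = 0.4, seed = s)
    } else {
        phantomSpec("wrapped_tube",
                    length_mm = 110 * (0.9 + 0.2 * u[1L]),
                    max_radius_mm = 13 * (0.9 + 0.2 * u[2L]),
                    wrap_offset_mm = 25, seed = s)
    }
}

# morph atlas attachments onto the subject and snap them to the bone
.morph_attachments <- function(study, max_snap_mm) {
    fit <- fitAffine(study@atlasLandmarks, study@landmarks)
    att <- applyTransform(fit, study@atlasAttachments)
    co <- att@coords
    for (i in seq_len(nrow(co)))
        co[i, ] <- suppressWarnings(
            snapToSurface(co[i, ], study@boneSurface, max_snap_mm))
    landmarkSet(att@names, co)
}

# analyse one subject x muscle: morph, standardize, cut, metrics
.analyse_subject <- function(study, muscle, config, subject_id) {
    att <- .morph_attachments(study, config$max_snap_mm)
    co <- landmarkCoords(att)
    axis <- makeAxis(co["origin", ], co["insertion", ])
    repeats <- study@repeats
    if (muscle == "iliopsoas") {
        lc <- landmarkCoords(study@landmarks)
        plane_point <- (lc["iliac_crest_R", ] + lc["iliac_crest_L", ]) / 2
        repeats <- lapply(repeats, standardizeProximal, axis = axis,
                          plane_point = plane_point)
    }
    series <- lapply(repeats, cutSeries, axis = axis,
                     step_fraction = config$step_fraction,
                     n_levels = config$n_levels)
    compareRepeats(series, subject_id = subject_id, muscle = muscle)
}

#' Per-level summary table of metric records
#'
#' Summarizes the tidy metric table across subjects: per muscle and level,
#' mean, min and max of each metric, plus a formatted
#' \code{"mean (min, max)"} string for each. Levels where every record is
#' flagged are emitted with NA markers and a warning.
#'
#' @param records a data.frame from [compareRepeats()] rows.
#' @return a data.frame with one row per muscle x level.
#' @export
summarizeRecords <- function(records) {
    fmt <- function(x) if (all(is.na(x))) "NA (NA, NA)" else
        sprintf("%.3f (%.3f, %.3f)", mean(x, na.rm = TRUE),
                min(x, na.rm = TRUE), max(x, na.rm = TRUE))
    out <- list()
    for (mus in unique(records$muscle)) {
        rm_ <- records[records$muscle == mus, ]
        for (lv in sort(unique(rm_$level_percent))) {
            rl <- rm_[rm_$level_percent == lv, ]
            if (all(rl$excluded))
                warning("muscle ", mus, " level ", lv,
                        "%: all records flagged; NA row emitted")
            stat <- function(x, f) if (all(is.na(x))) NA_real_ else
                f(x, na.rm = TRUE)
            out[[length(out) + 1L]] <- data.frame(
                muscle = mus, level_percent = lv,
                n = sum(!rl$excluded),
                ji_mean = stat(rl$ji_mean, mean),
                ji_min = stat(rl$ji_mean, min),
                ji_max = stat(rl$ji_mean, max),
                hd_mean = stat(rl$hd_mean_mm, mean),
                hd_min = stat(rl$hd_mean_mm, min),
                hd_max = stat(rl$hd_mean_mm, max),
                nvv_mean = stat(rl$nvv_percent, mean),
                nvv_min = stat(rl$nvv_percent, min),
                nvv_max = stat(rl$nvv_percent, max),
                ji = fmt(rl$ji_mean), hd_mm = fmt(rl$hd_mean_mm),
                nvv_percent = fmt(rl$nvv_percent))
        }
    }
    do.call(rbind, out)
}

# flatten list columns for CSV output
.flatten_records <- function(records) {
    np <- max(records$n_pairs)
    nr <- max(vapply(records$volumes_mm3, length, integer(1L)))
    flat <- records[, c("subject", "muscle", "level_percent", "ji_mean",
                        "hd_mean_mm", "nvv_percent", "n_pairs", "excluded")]
    grab <- function(col, n, prefix) {
        m <- t(vapply(records[[col]], function(x) {
            length(x) <- n
            as.numeric(x)
        }, numeric(n)))
        colnames(m) <- paste0(prefix, seq_len(n))
        m
    }
    cbind(flat, grab("pairwise_ji", np, "ji_pair"),
          grab("pairwise_hd_mm", np, "hd_pair"),
          grab("volumes_mm3", nr, "volume_rep"))
}

#' Run the full repeatability study end-to-end
#'
#' For every subject and muscle: generate (or load) the repeated
#' segmentations, morph and snap the atlas attachment points, standardize
#' the iliopsoas proximally, cut every repeat into the nested sub-volume
#' levels, compute the per-level agreement metrics, and run the
#' normality-gated statistical comparison per metric and muscle. A subject
#' failing any stage is excluded with a logged error; the run fails only if
#' fewer than 3 subjects survive for a muscle. Outputs are written to
#' \code{config$out_dir}: \code{metrics.csv}, \code{summary.csv},
#' \code{posthoc_<metric>_<muscle>.csv}, \code{stats.json},
#' \code{run_manifest.json} and \code{log.txt}; re-running with the same
#' config and seed reproduces them byte-identically.
#'
#' @param config a [studyConfig()].
#' @return invisibly, a list with \code{records} (tidy metric table),
#'   \code{summary}, \code{stats} (TestReports per muscle x metric) and
#'   \code{out_dir}.
#' @export
runStudy <- function(config) {
    stopifnot(inherits(config, "StudyConfig"))
    out_dir <- config$out_dir
    if (dir.exists(out_dir) &&
        length(list.files(out_dir, all.files = TRUE, no.. = TRUE)) > 0L &&
        !config$overwrite)
        stop("output directory ", out_dir, " is not empty")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    logs <- character(0L)
    note <- function(...) logs <<- c(logs, sprintf(...))

    all_records <- list()
    for (mus in config$muscles) {
        n_sub <- if (config$mode == "synthetic") config$n_subjects else
            length(config$study_dirs[[mus]])
        survived <- 0L
        for (s in seq_len(n_sub)) {
            sid <- sprintf("%s_%02d", mus, s)
            rec <- tryCatch({
                study <- if (config$mode == "synthetic") {
                    spec <- .subject_spec(mus, s, config$seed)
                    st <- makePhantom(spec, config$landmark_jitter_mm)
                    noise <- config$noise
                    noise$seed <- substreamSeed(config$seed, 1000L + s,
                                                match(mus, config$muscles))
                    att <- phantomAttachments(st)
                    ax <- makeAxis(landmarkCoords(att)["origin", ],
                                   landmarkCoords(att)["insertion", ])
                    st@repeats <- suppressMessages(
                        simulateRepeats(st@truth, ax, noise,
                                        config$n_repeats))
                    st
                } else readStudy(config$study_dirs[[mus]][s])
                suppressMessages(suppressWarnings(
                    .analyse_subject(study, mus, config, sid)))
            }, error = function(e) {
                note("subject %s excluded: %s", sid, conditionMessage(e))
                NULL
            })
            if (!is.null(rec)) {
                survived <- survived + 1L
                all_records[[length(all_records) + 1L]] <- rec
            }
        }
        note("muscle %s: %d of %d subjects analysed", mus, survived, n_sub)
        if (survived < 3L)
            stop("fewer than 3 subjects survived for muscle ", mus)
    }
    records <- do.call(rbind, all_records)
    summary_tab <- suppressWarnings(summarizeRecords(records))

    stats_out <- list()
    for (mus in config$muscles) {
        rm_ <- records[records$muscle == mus, ]
        for (metric in c("ji_mean", "hd_mean_mm", "nvv_percent")) {
            m <- suppressMessages(metricMatrix(rm_, metric))
            key <- paste(mus, metric, sep = ".")
            if (nrow(m) < 3L) {
                note("stats skipped for %s: <3 complete subjects", key)
                next
            }
            rep_ <- tryCatch(
                suppressMessages(suppressWarnings(
                    testLevels(m, config$alpha))),
                error = function(e) {
                    note("stats failed for %s: %s", key,
                         conditionMessage(e))
                    NULL
                })
            if (!is.null(rep_)) {
                stats_out[[key]] <- rep_
                utils::write.csv(
                    round(rep_$posthoc, 6),
                    file.path(out_dir, sprintf("posthoc_%s_%s.csv",
                                               sub("_.*", "", metric), mus)))
            }
        }
    }

    utils::write.csv(.flatten_records(records),
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
        lapply(stats_out, function(x) list(
            branch = x$branch, omnibus_stat = x$omnibus_stat,
            omnibus_p = x$omnibus_p, alpha = x$alpha,
            gate_p = as.numeric(x$gate))),
        file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    manifest <- list(package = "repseg",
                     version = as.character(utils::packageVersion("repseg")),
                     mode = config$mode, seed = config$seed,
                     n_subjects = config$n_subjects,
                     muscles = config$muscles,
                     n_repeats = config$n_repeats,
                     step_fraction = config$step_fraction,
                     n_levels = config$n_levels, alpha = config$alpha,
                     noise = unclass(config$noise))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(logs, file.path(out_dir, "log.txt"))
    invisible(list(records = records, summary = summary_tab,
                   stats = stats_out, out_dir = out_dir))
}
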