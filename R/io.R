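#' Read and write trial-event tables
#'
#' Trial tables are stored as tab-separated text with a dot decimal mark,
#' one row per presented trial, in the style of BIDS events files: `onset`
#' and `duration` in seconds plus the design and behavior columns
#' (`phase`, `object_id`, `scene_id`, `reward`, `run`, and the
#' phase-specific columns). `read_events()` validates the required columns
#' and parses `onset`/`duration` as numeric seconds.
#'
#' @param path file path.
#' @param table a trial table (see [make_design()]).
#' @return `read_events()` returns the trial table as a data frame;
#'   `write_events()` returns `path` invisibly.
#' @export
read_events <- function(path) {
  tb <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", "n/a"))
  required <- c("onset", "duration", "phase", "object_id", "scene_id",
                "reward", "run")
  missing <- setdiff(required, names(tb))
  if (length(missing)) {
    stop("events file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tb$onset <- as.numeric(tb$onset)
  tb$duration <- as.numeric(tb$duration)
  tb
}

#' @rdname read_events
#' @export
write_events <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers around \pkg{RNifti}. Volumes are returned as plain numeric
#' arrays with the image attributes preserved; voxel indices are handled
#' 1-based in R, world coordinates via the NIfTI affine.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param volume numeric array (3D or 4D); an existing image can be passed
#'   through `template` to carry the affine.
#' @param template optional image/array supplying header information.
#' @return `read_volume()` returns an `niftiImage` array.
#' @export
read_volume <- function(path) {
  RNifti::readNifti(path)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path, template = NULL) {
  img <- if (!is.null(template)) RNifti::asNifti(volume, reference = template)
         else RNifti::asNifti(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary ROI/brain mask
#'
#' Reads a NIfTI volume and binarizes it (`> threshold`); warns if the
#' on-disk values are not already 0/1.
#'
#' @param path file path.
#' @param threshold values strictly above this count as in-mask.
#' @return logical 3D array.
#' @export
read_mask <- function(path, threshold = 0) {
  v <- RNifti::readNifti(path)
  vals <- unique(as.numeric(v))
  if (!all(vals %in% c(0, 1))) {
    warning("mask ", path, " is not binary; binarizing at > ", threshold)
  }
  d <- dim(v)
  if (length(d) > 3) d <- d[1:3]
  if (length(d) < 3) d <- c(d, rep(1L, 3 - length(d)))
  array(as.numeric(v) > threshold, d)
}

#' Assemble and round-trip a pipeline run configuration
#'
#' A run configuration captures everything needed to reproduce a pipeline
#' run: design parameters, ground-truth profile and gain overrides, cohort
#' size, voxel count, permutation counts, and one explicit seed per
#' stochastic stage. Configurations round-trip losslessly through JSON.
#'
#' @param profile generator profile name (see [region_profile()]).
#' @param n_subjects,n_voxels cohort dimensions.
#' @param n_objects,n_scenes,n_runs,n_reps design parameters.
#' @param n_perm ROI permutation count.
#' @param seed master seed (per-stage seeds derive from it).
#' @param gains named list of [synthetic_truth()] overrides.
#' @return object of class `run_config` (named list).
#' @export
run_config <- function(profile = "null", n_subjects = 40, n_voxels = 150,
                       n_objects = 160, n_scenes = 4, n_runs = 4, n_reps = 2,
                       n_perm = 10000, seed = 1, gains = list()) {
  structure(list(profile = profile, n_subjects = n_subjects,
                 n_voxels = n_voxels, n_objects = n_objects,
                 n_scenes = n_scenes, n_runs = n_runs, n_reps = n_reps,
                 n_perm = n_perm, seed = seed, gains = gains),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$gains <- as.list(x$gains)
  structure(x, class = "run_config")
}
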