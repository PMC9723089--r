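# File I/O: NIfTI volumes via RNifti, DICOM series via the package's
# minimal reader, CSV score tables, JSON configuration and provenance.

#' Load a CT volume
#'
#' Reads a NIfTI file (`.nii` / `.nii.gz`) or a directory containing a
#' single-frame DICOM series. DICOM pixel data are converted to HU with
#' the rescale slope/intercept and slices are sorted by position.
#'
#' @param path NIfTI file path or DICOM series directory.
#' @param slice_levels optional per-slice level annotation.
#' @return a [ct_volume()].
#' @export
load_volume <- function(path, slice_levels = NULL) {
  if (dir.exists(path)) return(read_dicom_series(path, slice_levels))
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  if (length(dim(dat)) == 2) dat <- array(dat, c(dim(dat), 1L))
  pd <- RNifti::pixdim(img)
  ct_volume(dat, spacing = pd[seq_len(min(3, length(pd)))],
            slice_levels = slice_levels)
}

#' Save a volume, mask or label array as NIfTI
#'
#' HU volumes are stored as int16, masks and labels as uint8.
#'
#' @param vol a [ct_volume()] or plain array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param datatype `"int16"` (HU) or `"uint8"` (masks/labels).
#' @export
save_volume <- function(vol, path, datatype = "int16") {
  dat <- if (inherits(vol, "ct_volume")) vol$data else vol
  spacing <- if (inherits(vol, "ct_volume")) vol$spacing else c(1, 1, 1)
  img <- RNifti::asNifti(round(dat))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Nested configuration covering every stage; round-trips losslessly
#' through its JSON serialization.
#'
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    phantom = list(image_size = 128L, prevalence = 0.1,
                   lesion_delta = -8, lesion_fill = 0.8,
                   tissue_noise_sd = 2),
    preprocess = list(median_kernel = 3L, window_hu = c(0, 80), gamma = 0.6),
    model = list(width = 8L, input_size = 64L),
    training = list(lr0 = 0.2, lr_factor = 0.5, lr_step = 4L,
                    epochs = 10L, patience = 5L),
    scoring = list(threshold = 0.5, tau = 0.05),
    evaluation = list(n_boot = 2000L)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @param config a configuration list.
#' @return `load_config` returns the configuration merged over the
#'   defaults.
#' @export
load_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(modifyList(unclass(default_config()), user),
            class = "pipeline_config")
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# md5 of the canonical JSON serialization of a config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write the result files for one scored case
#'
#' Saves the binary mask aligned to the input grid (NIfTI), the region
#' score table (CSV), the ASPECTS summary, and a provenance JSON carrying
#' the config hash, seed and software versions — enough to reproduce the
#' artifact exactly.
#'
#' @param case_id case identifier.
#' @param mask binary array on the input grid.
#' @param scores a `region_score_vector`.
#' @param config the pipeline configuration used.
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
save_outputs <- function(case_id, mask, scores, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mask = file.path(dir, paste0(case_id, "_mask.nii.gz")),
             scores = file.path(dir, paste0(case_id, "_scores.csv")),
             summary = file.path(dir, paste0(case_id, "_aspects.csv")),
             provenance = file.path(dir, paste0(case_id, "_provenance.json")))
  save_volume(mask, paths["mask"], datatype = "uint8")
  write.csv(region_score_table(scores, case_id), paths["scores"],
            row.names = FALSE)
  write.csv(data.frame(case_id = case_id,
                       aspects_left = scores$aspects_left,
                       aspects_right = scores$aspects_right),
            paths["summary"], row.names = FALSE)
  jsonlite::write_json(list(case_id = case_id,
                            config_hash = config_hash(config),
                            seed = config$seed,
                            package_version =
                              as.character(utils::packageVersion("aspectsct")),
                            r_version = R.version.string),
                       paths["provenance"], auto_unbox = TRUE)
  paths
}
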