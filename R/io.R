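# On-disk interchange: NIfTI volumes, JSON ground-truth sidecars, cohort
# CSV tables.

#' Write a dynamic study to a directory
#'
#' The baseline volume goes to `ncct.nii.gz`, contrast frames to
#' `frame_###.nii.gz`, the hemodynamic ground truth and protocol to
#' `ground_truth.json`.
#'
#' @param study a `dynamic_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "dynamic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(vol, path) {
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = study$spacing), path)
  }
  wr(study$ncct, file.path(dir, "ncct.nii.gz"))
  for (k in seq_along(study$frames)) {
    wr(study$frames[[k]], file.path(dir, sprintf("frame_%03d.nii.gz", k)))
  }
  gt <- study$ground_truth
  jsonlite::write_json(list(
    study_id = study$study_id,
    frame_times = study$frame_times,
    protocol = unclass(study$protocol),
    spacing = study$spacing,
    grade = study$grade, label = study$label,
    arterial = gt$arterial, venous = gt$venous,
    fill = gt$fill, occluded_side = gt$occluded_side,
    collateral_amp = gt$collateral_amp, noise_sd = gt$noise_sd,
    artery_roi = gt$artery_roi, vein_roi = gt$vein_roi,
    phase_times = gt$phase_times
  ), file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dynamic study written by [write_study()]
#'
#' @param dir the study directory.
#' @return A `dynamic_study`.
#' @export
read_study <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  rd <- function(path) {
    v <- RNifti::readNifti(path)
    array(as.numeric(v), dim = dim(v))
  }
  frame_files <- sort(list.files(dir, pattern = "^frame_\\d+\\.nii\\.gz$",
                                 full.names = TRUE))
  structure(list(
    study_id = gt$study_id,
    protocol = structure(gt$protocol, class = "acq_protocol"),
    ncct = rd(file.path(dir, "ncct.nii.gz")),
    frames = lapply(frame_files, rd),
    frame_times = gt$frame_times,
    spacing = gt$spacing,
    ground_truth = list(arterial = as.list(gt$arterial),
                        venous = as.list(gt$venous),
                        fill = gt$fill, phase_times = as.list(gt$phase_times),
                        collateral_amp = gt$collateral_amp,
                        occluded_side = gt$occluded_side,
                        artery_roi = gt$artery_roi, vein_roi = gt$vein_roi,
                        noise_sd = gt$noise_sd),
    grade = as.integer(gt$grade),
    label = gt$label
  ), class = "dynamic_study")
}

#' Write the four subtracted phase volumes as NIfTI
#'
#' @param phase_set a `phase_volume_set`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phase_set <- function(phase_set, dir) {
  stopifnot(inherits(phase_set, "phase_volume_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ph in names(phase_set$volumes)) {
    RNifti::writeNifti(
      RNifti::asNifti(phase_set$volumes[[ph]], pixdim = phase_set$spacing),
      file.path(dir, sprintf("phase_%s.nii.gz", ph)))
  }
  invisible(dir)
}

#' Write / read the cohort record table as CSV
#'
#' @param records cohort data.frame from [generate_cohort()].
#' @param path CSV file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
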