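# Phase volume selection and NCCT subtraction with bone removal.

#' Select a contrast frame by index
#'
#' @param study a `dynamic_study`.
#' @param frame_index 1-based index into the contrast frames (the baseline
#'   non-contrast volume is not addressable here).
#' @return The 3-D attenuation array of that frame.
#' @export
select_volume <- function(study, frame_index) {
  n <- length(study$frames)
  if (!(frame_index >= 1 && frame_index <= n)) {
    stop("frame_index must be in 1..", n)
  }
  study$frames[[frame_index]]
}

#' Subtract the non-contrast baseline and remove bone
#'
#' Voxelwise `max(frame - ncct, 0)`, then every voxel whose baseline
#' attenuation is at or above `bone_hu` is set to 0. Negative differences
#' are clipped so noise does not pollute the downstream maximum-intensity
#' projections; volumes are simulated as co-registered, so a baseline
#' threshold suffices for bone removal.
#'
#' @param frame,ncct 3-D arrays of identical dimensions, HU.
#' @param bone_hu baseline attenuation threshold defining bone, HU.
#' @return Non-negative 3-D array of contrast enhancement, HU.
#' @export
subtract_ncct <- function(frame, ncct, bone_hu = 150) {
  if (!identical(dim(frame), dim(ncct))) {
    stop("frame and ncct dimensions differ")
  }
  out <- pmax(frame - ncct, 0)
  out[ncct >= bone_hu] <- 0
  out
}

#' Build the four subtracted phase volumes
#'
#' Applies [subtract_ncct()] to the frames named by the phase landmarks,
#' in the order arterial, arteriovenous, venous, late_venous.
#'
#' @param study a `dynamic_study`.
#' @param lm a `phase_landmarks` object valid for this study.
#' @param bone_hu passed to [subtract_ncct()].
#' @return A `phase_volume_set`: list with `volumes` (named list of four
#'   non-negative arrays) and `frame_index` (the source frame per phase).
#' @export
build_phase_set <- function(study, lm, bone_hu = 150) {
  stopifnot(inherits(lm, "phase_landmarks"))
  phases <- c("arterial", "arteriovenous", "venous", "late_venous")
  vols <- lapply(phases, function(ph) {
    subtract_ncct(select_volume(study, lm$frame_index[[ph]]), study$ncct,
                  bone_hu = bone_hu)
  })
  names(vols) <- phases
  structure(list(volumes = vols, frame_index = lm$frame_index,
                 spacing = study$spacing),
            class = "phase_volume_set")
}

#' @export
print.phase_volume_set <- function(x, ...) {
  cat("<phase_volume_set> ", paste(dim(x$volumes[[1]]), collapse = "x"),
      ", frames [", paste(x$frame_index, collapse = ", "), "]\n", sep = "")
  invisible(x)
}
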