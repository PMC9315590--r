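# Normalisation, maximum intensity projection, and four-phase stitching.

#' Window-normalise a volume to [0, 1]
#'
#' `clip((value - lo) / (hi - lo), 0, 1)`. The default window (0, 300) HU
#' spans the enhancement range of contrast-filled vessels on subtracted
#' volumes.
#'
#' @param volume 3-D array, HU.
#' @param window numeric length-2 `(lo, hi)`, `lo < hi`.
#' @return Array of the same dimensions with values in `[0, 1]`.
#' @export
normalize_volume <- function(volume, window = c(0, 300)) {
  lo <- window[1]; hi <- window[2]
  if (!(hi > lo)) stop("window must satisfy lo < hi")
  pmin(pmax((volume - lo) / (hi - lo), 0), 1)
}

#' Axial maximum intensity projection
#'
#' `out(y, x) = max over z of volume(z, y, x)`; the axial projection is
#' used because it carries the most collateral information of the
#' candidate projections.
#'
#' @param volume 3-D array indexed (z, y, x), typically normalised.
#' @return A `mip_image` matrix (y, x).
#' @export
mip <- function(volume) {
  d <- dim(volume)
  stopifnot(length(d) == 3)
  m <- matrix(volume, nrow = d[1])
  out <- matrix(apply(m, 2, max), nrow = d[2], ncol = d[3])
  structure(out, class = c("mip_image", class(out)))
}

#' Stitch the four phase MIPs into a 2x2 montage
#'
#' Row-major quadrant order: arterial (top-left), arteriovenous
#' (top-right), venous (bottom-left), late venous (bottom-right). Each
#' quadrant is bit-identical to its source projection; the square 2x2
#' layout keeps the classifier input square.
#'
#' @param mips named list with matrices `arterial`, `arteriovenous`,
#'   `venous`, `late_venous`, all of equal dimensions.
#' @return A `montage_image` matrix with twice the height and width of a
#'   single projection.
#' @export
stitch <- function(mips) {
  phases <- c("arterial", "arteriovenous", "venous", "late_venous")
  if (!all(phases %in% names(mips))) {
    stop("mips must contain all four phases: ", paste(phases, collapse = ", "))
  }
  dims <- lapply(mips[phases], dim)
  if (length(unique(dims)) != 1) stop("all four MIPs must share dimensions")
  out <- rbind(cbind(unclass(mips$arterial), unclass(mips$arteriovenous)),
               cbind(unclass(mips$venous), unclass(mips$late_venous)))
  structure(out, class = c("montage_image", class(out)))
}

#' MIPs and montage for a phase volume set
#'
#' Convenience composition: window-normalise each subtracted phase volume,
#' project it axially, and stitch the four projections.
#'
#' @param phase_set a `phase_volume_set` from [build_phase_set()].
#' @param window passed to [normalize_volume()].
#' @return List with `mips` (named list of four matrices) and `montage`.
#' @export
build_montage <- function(phase_set, window = c(0, 300)) {
  stopifnot(inherits(phase_set, "phase_volume_set"))
  mips <- lapply(phase_set$volumes, function(v) mip(normalize_volume(v, window)))
  list(mips = mips, montage = stitch(mips))
}

#' Write an image matrix as 8-bit grayscale PNG
#'
#' Values in `[0, 1]` are scaled by 255 and rounded half-up.
#'
#' @param image numeric matrix in `[0, 1]` (a MIP or montage).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  q <- floor(pmin(pmax(unclass(image), 0), 1) * 255 + 0.5) / 255
  png::writePNG(q, path)
  invisible(path)
}
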