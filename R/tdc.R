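# Time-density curves and hemodynamic phase landmarks.
#
# A time-density curve (TDC) samples the contrast enhancement (HU above the
# non-contrast baseline) at a vascular site across the contrast frames. Four
# phase landmarks are read off the arterial and venous TDCs: the arterial
# peak, the artery-vein curve crossing, the venous peak, and the first frame
# after the venous curve has settled into its washout plateau. Every
# landmark resolves to an acquired frame, because the downstream pipeline
# selects volumes, not interpolated time points.

#' Construct a time-density curve
#'
#' @param times contrast frame times, seconds, strictly increasing.
#' @param values enhancement above baseline, HU, same length as `times`.
#' @param site `"artery"` or `"vein"`.
#' @return A `tdc` object (list with `times`, `values`, `site`).
#' @export
tdc <- function(times, values, site = c("artery", "vein")) {
  site <- match.arg(site)
  stopifnot(length(times) == length(values), length(times) >= 3,
            all(diff(times) > 0))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 site = site), class = "tdc")
}

#' @export
print.tdc <- function(x, ...) {
  cat("<tdc> ", x$site, ", ", length(x$times), " frames, peak ",
      round(max(x$values), 1), " HU at t = ",
      x$times[which.max(x$values)], " s\n", sep = "")
  invisible(x)
}

#' Extract a time-density curve from a study
#'
#' The curve value at frame k is the mean attenuation over the region of
#' interest in frame k minus the mean over the same region in the baseline
#' non-contrast volume. ROIs are supplied by the caller (in practice the
#' earliest-enhancing artery and a large venous sinus are chosen and
#' checked by an operator); automatic vessel detection is not attempted.
#'
#' @param study a `dynamic_study`.
#' @param roi integer vector of linear voxel indices into the volume grid.
#' @param site `"artery"` or `"vein"`.
#' @return A [tdc()] object sampled at the study's contrast frame times.
#' @export
extract_tdc <- function(study, roi, site = c("artery", "vein")) {
  site <- match.arg(site)
  roi <- as.integer(roi)
  nvox <- length(study$ncct)
  if (length(roi) == 0) stop("roi must contain at least one voxel")
  if (any(roi < 1 | roi > nvox)) stop("roi indices out of volume bounds")
  base <- mean(study$ncct[roi])
  vals <- vapply(study$frames, function(f) mean(f[roi]) - base, numeric(1))
  tdc(study$frame_times, vals, site)
}

# Prominence of the local maximum at index i of series v: height above the
# higher of the two key saddles (the minimum between the peak and the
# nearest strictly higher ground on each side, or the series boundary).
.peak_prominence <- function(v, i) {
  left <- v[seq_len(i - 1)]
  higher_l <- which(left > v[i])
  base_l <- min(v[(if (length(higher_l)) max(higher_l) else 1):i])
  right <- v[seq(i, length(v))]
  higher_r <- which(right > v[i])
  base_r <- min(v[i:(if (length(higher_r)) i - 1 + min(higher_r) else length(v))])
  v[i] - max(base_l, base_r)
}

# Indices of interior local maxima, collapsing plateaus of tied values to
# their first sample.
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Quality-check a time-density curve
#'
#' A usable curve must be single-peaked ("bell-shaped", no double or
#' multiple peaks with prominence above `prominence_frac` of the global
#' maximum), must start rising after time zero, and should return towards a
#' plateau by the end of the acquisition. Curves failing the shape check
#' are re-selected upstream (a different vascular site is chosen).
#'
#' @param curve a [tdc()] object.
#' @param prominence_frac local maxima with prominence below this fraction
#'   of the global maximum are treated as noise ripples, not peaks.
#' @param plateau_frac final-value threshold (fraction of peak) for the
#'   `returns_to_plateau` flag.
#' @param rise_frac fraction of the peak regarded as the first real rise.
#' @return A `curve_qc` list: `n_peaks`, `is_bell_shaped`,
#'   `starts_after_zero`, `returns_to_plateau`.
#' @export
qc_curve <- function(curve, prominence_frac = 0.1, plateau_frac = 0.5,
                     rise_frac = 0.05) {
  stopifnot(inherits(curve, "tdc"))
  v <- curve$values
  vmax <- max(v)
  if (vmax <= 0) {
    return(structure(list(n_peaks = 0L, is_bell_shaped = FALSE,
                          starts_after_zero = FALSE,
                          returns_to_plateau = FALSE), class = "curve_qc"))
  }
  cand <- .local_maxima(v)
  prom <- vapply(cand, function(i) .peak_prominence(v, i), numeric(1))
  n_peaks <- sum(prom >= prominence_frac * vmax)
  imax <- which.max(v)
  interior <- imax > 1L && imax < length(v)
  rise <- which(v >= rise_frac * vmax)
  structure(list(
    n_peaks = as.integer(n_peaks),
    is_bell_shaped = n_peaks == 1L && interior,
    starts_after_zero = length(rise) > 0 && curve$times[rise[1]] > 0,
    returns_to_plateau = v[length(v)] <= plateau_frac * vmax
  ), class = "curve_qc")
}

#' Peak landmark of a bell-shaped curve
#'
#' The global-maximum sample; ties break toward the earlier frame. No
#' sub-frame interpolation is attempted because the landmark must name an
#' acquired volume.
#'
#' @param curve a [tdc()] that passes [qc_curve()].
#' @param check verify the bell-shape requirement (default `TRUE`).
#' @return List with `time` (s) and `frame_index` (1-based index into the
#'   contrast frames).
#' @export
find_peak <- function(curve, check = TRUE) {
  stopifnot(inherits(curve, "tdc"))
  if (check && !qc_curve(curve)$is_bell_shaped) {
    stop("curve is not bell-shaped; re-select the vascular site")
  }
  i <- which.max(curve$values)  # which.max already ties to the earlier frame
  list(time = curve$times[i], frame_index = i)
}

# Snap a time to the nearest member of `times[allowed]`; ties toward the
# earlier frame.
.snap_frame <- function(t_star, times, allowed) {
  idx <- which(allowed)
  d <- abs(times[idx] - t_star)
  i <- idx[which.min(d)]  # which.min ties to the earlier (lower-index) frame
  list(time = times[i], frame_index = i)
}

#' Artery-vein curve intersection landmark
#'
#' The earliest time strictly after the arterial peak and at or before the
#' venous peak where the linearly interpolated difference (arterial minus
#' venous) changes sign from non-negative to negative, snapped to the
#' nearest acquired frame within that interval (ties toward the earlier
#' frame). If the curves never cross there, the frame minimising the
#' absolute difference is returned and flagged.
#'
#' @param arterial,venous [tdc()] objects on the same time grid, both
#'   bell-shaped, with the arterial peak preceding the venous peak.
#' @param check verify preconditions (default `TRUE`).
#' @return List with `time`, `frame_index`, `t_star` (the interpolated
#'   crossing time, `NA` when no crossing exists) and `flagged`.
#' @export
find_av_intersection <- function(arterial, venous, check = TRUE) {
  stopifnot(inherits(arterial, "tdc"), inherits(venous, "tdc"),
            isTRUE(all.equal(arterial$times, venous$times)))
  if (check) {
    if (!qc_curve(arterial)$is_bell_shaped || !qc_curve(venous)$is_bell_shaped) {
      stop("both curves must be bell-shaped")
    }
  }
  ta <- find_peak(arterial, check = FALSE)$time
  tv <- find_peak(venous, check = FALSE)$time
  if (ta >= tv) stop("arterial peak must precede venous peak")
  times <- arterial$times
  d <- arterial$values - venous$values
  if (all(d == 0)) stop("curves are identical; intersection is degenerate")
  in_win <- times > ta & times <= tv
  t_star <- NA_real_
  for (k in seq_len(length(times) - 1L)) {
    t1 <- times[k]; t2 <- times[k + 1L]
    if (t2 <= ta || t1 > tv) next
    if (d[k] >= 0 && d[k + 1L] < 0) {
      tc <- t1 + (t2 - t1) * d[k] / (d[k] - d[k + 1L])
      if (tc > ta && tc <= tv) { t_star <- tc; break }
    }
  }
  if (!is.na(t_star)) {
    snap <- .snap_frame(t_star, times, in_win)
    c(snap, list(t_star = t_star, flagged = FALSE))
  } else {
    idx <- which(in_win)
    if (length(idx) == 0) idx <- seq_along(times)
    i <- idx[which.min(abs(d[idx]))]
    list(time = times[i], frame_index = i, t_star = NA_real_, flagged = TRUE)
  }
}

#' Late-venous plateau landmark
#'
#' The first frame strictly after the venous peak whose value has dropped
#' to at most `plateau_frac` of the peak and whose forward
#' finite-difference slope magnitude is at most `slope_tol` (the washout
#' plateau). At the final frame the backward difference is used. When no
#' frame qualifies the last frame is returned and flagged.
#'
#' @param venous a bell-shaped venous [tdc()].
#' @param plateau_frac fraction of the venous peak counted as plateau level.
#' @param slope_tol maximum plateau slope magnitude, HU/s.
#' @param check verify the bell-shape requirement (default `TRUE`).
#' @return List with `time`, `frame_index`, `flagged`.
#' @export
find_late_venous <- function(venous, plateau_frac = 0.5, slope_tol = 6,
                             check = TRUE) {
  stopifnot(inherits(venous, "tdc"))
  if (check && !qc_curve(venous)$is_bell_shaped) {
    stop("venous curve is not bell-shaped")
  }
  pk <- find_peak(venous, check = FALSE)
  n <- length(venous$times)
  if (pk$frame_index >= n) stop("venous peak at the last frame; no post-peak samples")
  v <- venous$values; tt <- venous$times
  for (i in seq(pk$frame_index + 1L, n)) {
    slope <- if (i < n) (v[i + 1L] - v[i]) / (tt[i + 1L] - tt[i])
             else (v[i] - v[i - 1L]) / (tt[i] - tt[i - 1L])
    if (v[i] <= plateau_frac * v[pk$frame_index] && abs(slope) <= slope_tol) {
      return(list(time = tt[i], frame_index = i, flagged = FALSE))
    }
  }
  list(time = tt[n], frame_index = n, flagged = TRUE)
}

#' Derive the four phase landmarks from arterial and venous curves
#'
#' Composes the peak, intersection, and plateau finders and enforces the
#' phase ordering invariant: arterial peak < artery-vein intersection <=
#' venous peak < late venous, with distinct arterial and venous frames. A
#' venous peak at or before the arterial peak indicates mis-selected
#' curves and is rejected (the operator re-selects the sites).
#'
#' @inheritParams find_av_intersection
#' @param plateau_frac,slope_tol passed to [find_late_venous()].
#' @return A `phase_landmarks` object: per-phase `times` and
#'   `frame_index` vectors (named arterial, arteriovenous, venous,
#'   late_venous) plus `flags` from the fallback rules.
#' @export
landmarks <- function(arterial, venous, plateau_frac = 0.5, slope_tol = 6) {
  qa <- qc_curve(arterial); qv <- qc_curve(venous)
  if (!qa$is_bell_shaped) stop("arterial curve failed quality control")
  if (!qv$is_bell_shaped) stop("venous curve failed quality control")
  pa <- find_peak(arterial, check = FALSE)
  pv <- find_peak(venous, check = FALSE)
  if (pv$time <= pa$time) {
    stop("venous peak does not follow arterial peak; curves look mis-selected")
  }
  av <- find_av_intersection(arterial, venous, check = FALSE)
  lv <- find_late_venous(venous, plateau_frac = plateau_frac,
                         slope_tol = slope_tol, check = FALSE)
  times <- c(arterial = pa$time, arteriovenous = av$time,
             venous = pv$time, late_venous = lv$time)
  idx <- c(arterial = pa$frame_index, arteriovenous = av$frame_index,
           venous = pv$frame_index, late_venous = lv$frame_index)
  if (!(times[1] < times[2] && times[2] <= times[3] && times[3] < times[4])) {
    stop("phase ordering violated: ",
         paste(names(times), round(times, 2), sep = "=", collapse = ", "))
  }
  if (idx[1] == idx[3]) stop("arterial and venous phases resolve to the same frame")
  structure(list(times = times, frame_index = idx,
                 flags = c(av_no_crossing = av$flagged,
                           late_venous_fallback = lv$flagged)),
            class = "phase_landmarks")
}

#' @export
print.phase_landmarks <- function(x, ...) {
  cat("<phase_landmarks>\n")
  for (ph in names(x$times)) {
    cat(sprintf("  %-14s t = %5.1f s  (frame %d)\n", ph, x$times[[ph]],
                x$frame_index[[ph]]))
  }
  if (any(x$flags)) cat("  flags:", paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  invisible(x)
}

#' Serialize curves and landmarks to JSON
#'
#' @param arterial,venous [tdc()] objects.
#' @param lm a `phase_landmarks` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(arterial, venous, lm, path) {
  jsonlite::write_json(list(
    arterial = list(times = arterial$times, values = arterial$values),
    venous = list(times = venous$times, values = venous$values),
    landmarks = list(times = as.list(lm$times),
                     frame_index = as.list(lm$frame_index),
                     flags = as.list(lm$flags))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
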