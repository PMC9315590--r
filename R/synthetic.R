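#' @useDynLib collat4d, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom rgamma
NULL

# ---------------------------------------------------------------------------
# Head phantom geometry
# ---------------------------------------------------------------------------

# Normalised ellipsoidal radius for every voxel of a (z, y, x) grid.
# rho = 1 on the outer skull surface.
.head_rho <- function(size) {
  nz <- size[1]; ny <- size[2]; nx <- size[3]
  z2 <- ((seq_len(nz) - (nz + 1) / 2) / (0.48 * nz))^2
  y2 <- ((seq_len(ny) - (ny + 1) / 2) / (0.46 * ny))^2
  x2 <- ((seq_len(nx) - (nx + 1) / 2) / (0.46 * nx))^2
  sqrt(outer(outer(z2, y2, "+"), x2, "+"))
}

#' Brain mask of the synthetic head phantom
#'
#' @param size integer vector (z, y, x) of grid dimensions.
#' @return Logical array of the same dimensions, `TRUE` inside the brain.
#' @export
brain_mask <- function(size) {
  .head_rho(size) <= 0.82
}

# Bone shell mask (skull) of the phantom.
.bone_mask <- function(size) {
  rho <- .head_rho(size)
  rho > 0.86 & rho <= 1
}

#' Occluded and mirrored contralateral territory masks
#'
#' The occluded territory is one lateral half of the brain mask relative to
#' the sagittal mid-plane; the contralateral territory is its mirror image
#' across that plane.
#'
#' @param size integer vector (z, y, x).
#' @param occluded_side `"left"` (lower x indices) or `"right"`.
#' @return List with logical arrays `occluded` and `contralateral`.
#' @export
territory_masks <- function(size, occluded_side = c("left", "right")) {
  occluded_side <- match.arg(occluded_side)
  brain <- brain_mask(size)
  nx <- size[3]
  xs <- slice.index(brain, 3)
  half <- if (occluded_side == "left") xs <= nx / 2 else xs > nx / 2 + (nx %% 2)
  mirror_x <- nx + 1L - seq_len(nx)
  occ <- brain & half
  con <- occ[, , mirror_x, drop = FALSE]
  list(occluded = occ, contralateral = con & brain)
}

# Rasterize a straight segment between two voxel coordinates (z, y, x).
# Returns unique linear indices into a (z, y, x) array.
.seg_voxels <- function(p0, p1, size) {
  n <- max(2L, ceiling(2 * sqrt(sum((p1 - p0)^2))))
  tt <- seq(0, 1, length.out = n)
  zz <- pmin(pmax(round(p0[1] + tt * (p1[1] - p0[1])), 1L), size[1])
  yy <- pmin(pmax(round(p0[2] + tt * (p1[2] - p0[2])), 1L), size[2])
  xx <- pmin(pmax(round(p0[3] + tt * (p1[3] - p0[3])), 1L), size[3])
  unique(zz + (yy - 1L) * size[1] + (xx - 1L) * size[1] * size[2])
}

# Coordinates (z, y, x) of a linear index.
.idx_coords <- function(idx, size) {
  idx0 <- idx - 1L
  z <- idx0 %% size[1]
  y <- (idx0 %/% size[1]) %% size[2]
  x <- idx0 %/% (size[1] * size[2])
  cbind(z + 1L, y + 1L, x + 1L)
}

# Random tubular segments with endpoints sampled from `pool` (linear
# indices of candidate voxels); returns the union of rasterized voxels.
.random_segments <- function(n_seg, pool, size) {
  coords <- .idx_coords(pool, size)
  out <- integer(0)
  for (i in seq_len(n_seg)) {
    ends <- sample.int(nrow(coords), 2L)
    out <- c(out, .seg_voxels(coords[ends[1], ], coords[ends[2], ], size))
  }
  unique(out)
}

# ---------------------------------------------------------------------------
# Hemodynamic ground truth
# ---------------------------------------------------------------------------

# Analytic phase times implied by a pair of gamma-variate compartment
# curves: arterial peak, artery-vein crossing, venous peak, and the first
# time the venous curve satisfies the plateau rule (value <= plateau_frac *
# peak and |slope| <= slope_tol). `late_flagged` records the fallback to the
# end of the acquisition when the plateau is never reached.
.analytic_phase_times <- function(arterial, venous, t_end = 60,
                                  plateau_frac = 0.5, slope_tol = 6) {
  t_a <- gv_peak_time(arterial)
  t_v <- gv_peak_time(venous)
  stopifnot(t_a < t_v)
  d <- function(t) gv_eval(t, arterial) - gv_eval(t, venous)
  t_av <- stats::uniroot(d, lower = t_a + 1e-6, upper = t_v, tol = 1e-8)$root
  tt <- seq(t_v, t_end, by = 0.01)
  vv <- gv_eval(tt, venous)
  slope <- c(diff(vv) / diff(tt), 0)
  ok <- which(vv <= plateau_frac * venous$A & abs(slope) <= slope_tol)
  late_flagged <- length(ok) == 0
  t_late <- if (late_flagged) t_end else tt[ok[1]]
  list(arterial = t_a, arteriovenous = t_av, venous = t_v,
       late_venous = t_late, late_flagged = late_flagged)
}

# Collateral fill fraction at time t: a right-continuous step function,
# 0 before the first jump time and fill[k] from the k-th jump time on.
# The first jump is placed at the arterial onset (collaterals begin filling
# with arterial inflow), the remaining jumps at the arteriovenous, venous,
# and late-venous phase times, so the fraction observed AT each phase
# equals the corresponding fill entry.
.fill_at_time <- function(t, fill, jump_times) {
  vapply(t, function(ti) {
    k <- sum(jump_times <= ti)
    if (k == 0) 0 else fill[k]
  }, numeric(1))
}

#' Collateral grade from per-phase filling fractions
#'
#' Maps the fraction of the occluded territory's collateral vessels that is
#' opacified at the arterial, arteriovenous, venous, and late-venous phases
#' to the 0-4 collateral grade used for dynamic multiphase CTA: 0 = no or
#' few collaterals at any stage; 1 = partial filling only by the late
#' venous phase; 2 = partial filling already before the venous phase;
#' 3 = complete filling by the late venous phase; 4 = complete filling
#' before the venous phase.
#'
#' @param fill numeric length-4, non-decreasing, in `[0, 1]`: fraction
#'   opacified at each of the four phases.
#' @param thresholds named numeric: `few` (below which filling counts as
#'   absent) and `complete` (at or above which filling counts as complete).
#'   The verbal scale is qualitative; these cut-points are configurable.
#' @return Integer grade in 0..4.
#' @examples
#' assign_grade(c(0, 0, 0, 0))          # 0
#' assign_grade(c(0.95, 1, 1, 1))       # 4
#' assign_grade(c(0.2, 0.3, 0.5, 0.95)) # 3
#' @export
assign_grade <- function(fill, thresholds = c(few = 0.1, complete = 0.9)) {
  stopifnot(length(fill) == 4, all(fill >= 0), all(fill <= 1))
  if (any(diff(fill) < -1e-9)) {
    stop("fill fractions must be non-decreasing across phases")
  }
  few <- thresholds[["few"]]; complete <- thresholds[["complete"]]
  before_venous <- fill[2]  # best filling at or before the arteriovenous phase
  if (max(fill) < few) return(0L)
  if (before_venous >= complete) return(4L)
  if (fill[4] >= complete) return(3L)
  if (before_venous >= few) return(2L)
  1L
}

# Draw a fill-fraction vector consistent with a target grade. `contrast`
# "strong" pushes good/poor studies toward the extremes of their grade.
.draw_fill <- function(grade, contrast = "typical") {
  f <- switch(as.character(grade),
    "0" = if (contrast == "strong") sort(runif(4, 0, 0.02))
          else sort(runif(4, 0, 0.08)),
    "1" = {
      lo <- sort(runif(2, 0, 0.08)); hi <- sort(runif(2, 0.15, 0.6))
      c(lo, hi)
    },
    "2" = c(sort(runif(2, 0.15, 0.6)), sort(runif(2, 0.6, 0.85))),
    "3" = c(sort(runif(2, 0.15, 0.6)), runif(1, 0.6, 0.85), runif(1, 0.92, 1)),
    "4" = {
      if (contrast == "strong") {
        f1 <- runif(1, 0.95, 0.98)
      } else {
        f1 <- runif(1, 0.88, 0.96)
      }
      f2 <- runif(1, max(f1, 0.92), 1)
      f34 <- sort(runif(2, f2, 1))
      c(f1, f2, f34)
    },
    stop("grade must be an integer in 0..4"))
  stopifnot(assign_grade(f) == grade)
  f
}

# Draw compartment gamma-variate parameters. Ranges keep the arterial peak
# inside the 11-36 s window and the venous peak inside the 40-60 s window
# of the acquisition protocol, with venous onset after arterial onset.
.draw_tdc_params <- function() {
  t0a <- runif(1, 9, 12)
  arterial <- list(t0 = t0a, alpha = runif(1, 2.6, 3.4),
                   beta = runif(1, 2.3, 3.1), A = runif(1, 170, 240))
  venous <- list(t0 = t0a + runif(1, 9, 10.5), alpha = runif(1, 6, 6.3),
                 beta = runif(1, 3.85, 4.05), A = runif(1, 90, 130))
  list(arterial = arterial, venous = venous)
}

# ---------------------------------------------------------------------------
# Study generation
# ---------------------------------------------------------------------------

#' Generate one labelled synthetic dynamic 4D-CTA study
#'
#' Renders a baseline non-contrast volume plus one contrast volume per
#' protocol frame time on a (z, y, x) grid: an ellipsoidal bone shell at
#' 900 HU, parenchyma at 30 HU with additive Gaussian noise, tubular
#' arterial and venous vessel trees whose added attenuation follows
#' gamma-variate compartment curves, and - in the occluded lateral half of
#' the brain - collateral vessels that opacify progressively according to
#' the per-phase filling fraction implied by the study's collateral grade.
#' Arteries fill antegradely only in the healthy hemisphere (the occlusion
#' abolishes antegrade filling distally); opacified collateral voxels keep
#' their enhancement through the end of the acquisition, emulating the
#' delayed washout seen on the affected side.
#'
#' @param label `"good"` (grade 3-4) or `"poor"` (grade 0-2).
#' @param size integer (z, y, x) grid dimensions, each axis at least
#'   (8, 32, 32). The default keeps volumes desk-scale; the in-plane
#'   512 x 512 clinical matrix is available by request.
#' @param protocol an [make_protocol()] object.
#' @param seed integer; the study is voxel-identical across runs for a
#'   given seed.
#' @param grade optional integer 0-4 consistent with `label`; drawn
#'   uniformly from the label's grade set when `NULL`.
#' @param fill optional length-4 non-decreasing filling fractions; drawn to
#'   match `grade` when `NULL`.
#' @param noise_sd additive Gaussian noise, HU.
#' @param contrast `"typical"` or `"strong"`; `"strong"` pushes the drawn
#'   grade and filling fractions to the class extremes (grade 4 vs 0).
#' @return A `dynamic_study` object: fields `ncct` (3-D array, HU),
#'   `frames` (list of 3-D arrays), `frame_times` (s), `protocol`,
#'   `spacing` (mm), `ground_truth` (compartment curve parameters, filling
#'   fractions, analytic phase times, vessel ROIs, occluded side), `grade`
#'   and `label`.
#' @export
generate_study <- function(label = c("good", "poor"), size = c(16, 64, 64),
                           protocol = make_protocol(), seed = 1,
                           grade = NULL, fill = NULL, noise_sd = 3,
                           contrast = c("typical", "strong")) {
  label <- match.arg(label)
  contrast <- match.arg(contrast)
  size <- as.integer(size)
  if (length(size) != 3 || any(size < c(8L, 32L, 32L))) {
    stop("size must be (z, y, x) with each axis at least (8, 32, 32)")
  }
  withr::with_seed(seed, {
    if (is.null(grade)) {
      grade <- if (contrast == "strong") {
        if (label == "good") 4L else 0L
      } else {
        if (label == "good") sample(3:4, 1) else sample(0:2, 1)
      }
    }
    grade <- as.integer(grade)
    if ((label == "good") != (grade >= 3L)) {
      stop("label must be 'good' iff grade >= 3")
    }
    if (is.null(fill)) fill <- .draw_fill(grade, contrast)
    stopifnot(assign_grade(fill) == grade)

    params <- .draw_tdc_params()
    phase_times <- .analytic_phase_times(params$arterial, params$venous,
                                         t_end = max(unclass(protocol)))
    occluded_side <- sample(c("left", "right"), 1)
    healthy_side <- setdiff(c("left", "right"), occluded_side)

    brain <- brain_mask(size)
    bone <- .bone_mask(size)
    rho <- .head_rho(size)
    nvox <- prod(size)
    nx <- size[3]
    xs <- slice.index(brain, 3)
    left <- xs <= nx / 2
    hemi <- list(left = which(brain & left), right = which(brain & !left))

    # Vessel voxel sets. Arteries: a designated trunk (the TDC sampling
    # site) plus random branches, healthy hemisphere only. Veins: a midline
    # sinus (the venous sampling site) plus random tributaries in both
    # hemispheres. Collaterals: random segments in the occluded territory.
    pool_h <- hemi[[healthy_side]]
    co_h <- .idx_coords(pool_h, size)
    trunk_lo <- co_h[which.min(abs(co_h[, 1] - 0.3 * size[1]) +
                               abs(co_h[, 2] - 0.5 * size[2])), ]
    trunk_hi <- co_h[which.min(abs(co_h[, 1] - 0.75 * size[1]) +
                               abs(co_h[, 2] - 0.45 * size[2])), ]
    trunk <- .seg_voxels(trunk_lo, trunk_hi, size)
    arteries <- unique(c(trunk, .random_segments(4L, pool_h, size)))
    arteries <- intersect(arteries, which(brain))

    sinus <- .seg_voxels(c(round(0.7 * size[1]), round(0.3 * size[2]), round(nx / 2)),
                         c(round(0.7 * size[1]), round(0.7 * size[2]), round(nx / 2)),
                         size)
    sinus <- intersect(sinus, which(brain))
    veins <- unique(c(sinus,
                      .random_segments(2L, hemi$left, size),
                      .random_segments(2L, hemi$right, size)))
    veins <- setdiff(intersect(veins, which(brain)), arteries)

    pool_o <- hemi[[occluded_side]]
    collaterals <- .random_segments(6L, pool_o, size)
    collaterals <- setdiff(intersect(collaterals, pool_o),
                           c(arteries, veins))
    coll_order <- sample(collaterals)
    coll_amp <- runif(1, 140, 180)

    mid5 <- function(v) v[pmin(length(v), pmax(1L, round(length(v) / 2) + (-2:2)))]
    artery_roi <- unique(intersect(mid5(trunk), arteries))
    if (length(artery_roi) == 0) artery_roi <- arteries[seq_len(min(5, length(arteries)))]
    vein_roi <- unique(intersect(mid5(sinus), veins))
    if (length(vein_roi) == 0) vein_roi <- veins[seq_len(min(5, length(veins)))]

    base <- rep(-1000, nvox)          # air
    base[rho <= 0.86] <- 30           # soft tissue and parenchyma
    base[bone] <- 900                 # skull
    base[c(arteries, veins, collaterals)] <- 40  # unenhanced blood

    noise <- function() if (noise_sd > 0) rnorm(nvox, 0, noise_sd) else 0
    ncct <- array(base + noise(), dim = size)

    times <- contrast_times(protocol)
    fill_jumps <- c(params$arterial$t0, phase_times$arteriovenous,
                    phase_times$venous, phase_times$late_venous)
    frames <- vector("list", length(times))
    for (k in seq_along(times)) {
      t <- times[k]
      v <- base
      v[arteries] <- v[arteries] + gv_eval(t, params$arterial)
      v[veins] <- v[veins] + gv_eval(t, params$venous)
      n_on <- floor(.fill_at_time(t, fill, fill_jumps) * length(coll_order) + 0.5)
      if (n_on > 0) {
        on <- coll_order[seq_len(n_on)]
        v[on] <- v[on] + coll_amp
      }
      frames[[k]] <- array(v + noise(), dim = size)
    }

    spacing <- c(140 / size[1], 240 / size[2], 240 / size[3])
    structure(list(
      study_id = sprintf("study-%08x", seed),
      protocol = protocol,
      ncct = ncct,
      frames = frames,
      frame_times = times,
      spacing = spacing,
      ground_truth = list(
        arterial = params$arterial, venous = params$venous,
        fill = fill, phase_times = phase_times,
        collateral_amp = coll_amp, occluded_side = occluded_side,
        artery_roi = artery_roi, vein_roi = vein_roi,
        noise_sd = noise_sd),
      grade = grade,
      label = label
    ), class = "dynamic_study")
  })
}

#' @export
print.dynamic_study <- function(x, ...) {
  cat("<dynamic_study> ", x$study_id, ": ", length(x$frames),
      " contrast frames of ", paste(dim(x$ncct), collapse = "x"),
      ", grade ", x$grade, " (", x$label, "), occluded ",
      x$ground_truth$occluded_side, "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cohorts
# ---------------------------------------------------------------------------

# Covariate model qualitatively matching the clinical baseline table of a
# 92-patient anterior-circulation stroke cohort (configurable; `pooled`
# holds the no-group-effect distributions used for calibration checks).
.covariate_model <- list(
  poor = list(age = c(69.45, 14.05), male_p = 30 / 42,
              nihss = c(shape = 2.2, scale = 5.5),
              onset = c(17, 11, 14), artery = c(3, 28, 10, 1),
              toast = c(25, 15, 2), treatment = c(5, 9, 1, 27),
              hemorrhage_p = 13 / 42),
  good = list(age = c(63.54, 12.82), male_p = 31 / 50,
              nihss = c(shape = 1.3, scale = 4.0),
              onset = c(15, 8, 27), artery = c(9, 36, 3, 0),
              toast = c(38, 9, 3), treatment = c(3, 13, 2, 32),
              hemorrhage_p = 6 / 50),
  pooled = list(age = c(66.24, 13.64), male_p = 61 / 92,
                nihss = c(shape = 1.7, scale = 5.0),
                onset = c(32, 19, 41), artery = c(14, 64, 13, 1),
                toast = c(63, 24, 5), treatment = c(8, 22, 3, 59),
                hemorrhage_p = 19 / 92)
)

.onset_levels <- c("<6h", "6-24h", ">24h")
.artery_levels <- c("ICA", "MCA", "ICA+MCA", "ICA+MCA+ACA")
.toast_levels <- c("LAA", "CE", "SOE")
.treatment_levels <- c("thrombolysis", "endovascular", "bridging", "conservative")

.draw_covariates <- function(label, covariate_effects = TRUE) {
  m <- if (covariate_effects) .covariate_model[[label]] else .covariate_model$pooled
  list(
    age = round(min(95, max(18, rnorm(1, m$age[1], m$age[2]))), 1),
    sex = if (runif(1) < m$male_p) "M" else "F",
    nihss = min(42L, as.integer(round(rgamma(1, shape = m$nihss[["shape"]],
                                             scale = m$nihss[["scale"]])))),
    onset_bin = sample(.onset_levels, 1, prob = m$onset),
    artery = sample(.artery_levels, 1, prob = m$artery + 0.25),
    toast = sample(.toast_levels, 1, prob = m$toast),
    treatment = sample(.treatment_levels, 1, prob = m$treatment),
    hemorrhagic_transformation = runif(1) < m$hemorrhage_p
  )
}

# Per-study sampling plan for a cohort: ids, labels, grades, filling
# fractions, per-study seeds, and the covariate table.
.cohort_plan <- function(n_good, n_poor, seed = 1,
                         contrast = c("typical", "strong"),
                         covariate_effects = TRUE) {
  contrast <- match.arg(contrast)
  if (n_good < 1 || n_poor < 1) stop("both classes must be non-empty")
  if (n_good + n_poor < 4) stop("cohort must contain at least 4 studies")
  n <- n_good + n_poor
  withr::with_seed(seed, {
    labels <- c(rep("good", n_good), rep("poor", n_poor))
    grades <- vapply(labels, function(lb) {
      if (contrast == "strong") {
        if (lb == "good") 4L else 0L
      } else if (lb == "good") sample(3:4, 1) else sample(0:2, 1)
    }, integer(1))
    fills <- lapply(grades, .draw_fill, contrast = contrast)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    cov <- lapply(labels, .draw_covariates, covariate_effects = covariate_effects)
    records <- data.frame(
      study_id = sprintf("P%03d", seq_len(n)),
      age = vapply(cov, `[[`, numeric(1), "age"),
      sex = vapply(cov, `[[`, character(1), "sex"),
      nihss = vapply(cov, `[[`, integer(1), "nihss"),
      onset_bin = vapply(cov, `[[`, character(1), "onset_bin"),
      artery = vapply(cov, `[[`, character(1), "artery"),
      toast = vapply(cov, `[[`, character(1), "toast"),
      treatment = vapply(cov, `[[`, character(1), "treatment"),
      hemorrhagic_transformation =
        vapply(cov, `[[`, logical(1), "hemorrhagic_transformation"),
      grade = grades,
      label = labels,
      stringsAsFactors = FALSE
    )
    list(records = records, fills = fills, seeds = seeds, contrast = contrast)
  })
}

#' Generate a labelled synthetic cohort
#'
#' Draws a per-study sampling plan (grades, filling fractions, covariates,
#' per-study seeds) and renders one [generate_study()] per patient. The
#' covariate table qualitatively matches the baseline characteristics of a
#' 92-patient stroke cohort (ages, NIHSS, onset bins, occluded artery,
#' TOAST type, treatment, hemorrhagic transformation), with group effects
#' that can be switched off for calibration experiments.
#'
#' @inheritParams generate_study
#' @param n_good,n_poor class sizes (each at least 1, total at least 4).
#' @param covariate_effects draw covariates conditional on the collateral
#'   label (`TRUE`, default) or from pooled label-free distributions.
#' @param keep_volumes if `FALSE`, skip volume rendering and return only
#'   the cohort record table (fast; used for statistics-only work).
#' @return List with `studies` (list of `dynamic_study`, or `NULL` when
#'   `keep_volumes = FALSE`) and `records` (data.frame, one row per study).
#' @examples
#' rec <- generate_cohort(3, 3, seed = 1, keep_volumes = FALSE)$records
#' table(rec$label)
#' @export
generate_cohort <- function(n_good, n_poor, size = c(16, 64, 64),
                            protocol = make_protocol(), seed = 1,
                            contrast = c("typical", "strong"), noise_sd = 3,
                            covariate_effects = TRUE, keep_volumes = TRUE) {
  contrast <- match.arg(contrast)
  plan <- .cohort_plan(n_good, n_poor, seed = seed, contrast = contrast,
                       covariate_effects = covariate_effects)
  studies <- NULL
  if (keep_volumes) {
    studies <- lapply(seq_len(nrow(plan$records)), function(i) {
      s <- generate_study(plan$records$label[i], size = size,
                          protocol = protocol, seed = plan$seeds[i],
                          grade = plan$records$grade[i], fill = plan$fills[[i]],
                          noise_sd = noise_sd, contrast = contrast)
      s$study_id <- plan$records$study_id[i]
      s
    })
  }
  list(studies = studies, records = plan$records, plan = plan)
}
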