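# End-to-end experiment driver: synthetic cohort -> landmarks -> phase
# subtraction -> MIP montage -> residual classifier -> Monte Carlo
# cross-validated metrics.

#' Preprocess one study to classifier inputs
#'
#' Extracts the arterial and venous time-density curves at the study's
#' vessel sampling sites, derives the four phase landmarks, builds the
#' subtracted bone-removed phase volumes, and returns the per-phase MIPs
#' and the stitched montage.
#'
#' @param study a `dynamic_study`.
#' @param window normalisation window in HU, passed to
#'   [normalize_volume()].
#' @param plateau_frac,slope_tol passed to [landmarks()].
#' @param bone_hu passed to [build_phase_set()].
#' @return List with `montage`, `mips`, `landmarks`, `arterial`/`venous`
#'   curves.
#' @export
study_to_inputs <- function(study, window = c(0, 300), plateau_frac = 0.5,
                            slope_tol = 6, bone_hu = 150) {
  arterial <- extract_tdc(study, study$ground_truth$artery_roi, "artery")
  venous <- extract_tdc(study, study$ground_truth$vein_roi, "vein")
  lm <- landmarks(arterial, venous, plateau_frac = plateau_frac,
                  slope_tol = slope_tol)
  ps <- build_phase_set(study, lm, bone_hu = bone_hu)
  mm <- build_montage(ps, window = window)
  list(montage = mm$montage, mips = mm$mips, landmarks = lm,
       arterial = arterial, venous = venous)
}

#' Run a Monte Carlo cross-validated classification experiment
#'
#' Generates a labelled synthetic cohort, preprocesses every study to its
#' montage and phase MIPs, then repeatedly splits the cohort 70/30
#' (stratified), trains a fresh classifier per split, and scores the held
#' out studies. Volumes are rendered one study at a time and discarded
#' after preprocessing, so memory stays flat in the cohort size.
#'
#' @param n_good,n_poor class sizes.
#' @param variant `"single"` or `"multi"` (see [network_config()]).
#' @param size study grid (z, y, x); in-plane size fixes the MIP quadrant
#'   size and hence the montage side.
#' @param n_iter Monte Carlo iterations.
#' @param ratio training fraction.
#' @param seed master seed; cohort, splits, and per-iteration network
#'   initialisation are all derived from it.
#' @param contrast passed to the cohort generator (`"strong"` separates
#'   the classes maximally).
#' @param base_width classifier channel width.
#' @param noise_sd acquisition noise, HU.
#' @param window MIP normalisation window, HU.
#' @return List with `report` (a `metrics_report`), `records`,
#'   `splits`, and `config`.
#' @export
run_experiment <- function(n_good = 40, n_poor = 40,
                           variant = c("single", "multi"),
                           size = c(16, 64, 64), n_iter = 5, ratio = 0.7,
                           seed = 1, contrast = "strong", base_width = 8,
                           noise_sd = 3, window = c(0, 300)) {
  variant <- match.arg(variant)
  plan <- .cohort_plan(n_good, n_poor, seed = seed, contrast = contrast)
  records <- plan$records
  n <- nrow(records)
  montages <- vector("list", n)
  mips <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_study(records$label[i], size = size, seed = plan$seeds[i],
                        grade = records$grade[i], fill = plan$fills[[i]],
                        noise_sd = noise_sd, contrast = plan$contrast)
    inp <- study_to_inputs(s, window = window)
    montages[[i]] <- inp$montage
    mips[[i]] <- inp$mips
  }
  montage_side <- nrow(montages[[1]])
  quad_side <- montage_side / 2L

  splits <- mc_splits(seq_len(n), labels = records$label, ratio = ratio,
                      n_iter = n_iter, seed = seed + 1L)
  iter_metrics <- list()
  rocs <- list()
  for (sp in splits) {
    cfg <- network_config(variant,
                          input_side = if (variant == "single") montage_side
                                       else quad_side,
                          base_width = base_width,
                          seed = seed + 7919L * sp$iteration)
    model <- build_classifier(cfg)
    if (variant == "single") {
      model <- train_classifier(model, montages[sp$train],
                                records$label[sp$train])
      pred <- predict(model, montages[sp$test])
    } else {
      phase_x <- function(idx) {
        out <- lapply(.phases, function(ph) {
          .stack_images(lapply(mips[idx], `[[`, ph))
        })
        names(out) <- .phases
        out
      }
      model <- train_classifier(model, phase_x(sp$train),
                                records$label[sp$train])
      pred <- predict(model, phase_x(sp$test))
    }
    truth <- records$label[sp$test]
    cm <- confusion(truth, pred$label)
    ra <- roc_auc(pred$p_good, truth)
    iter_metrics[[sp$iteration]] <- c(metrics(cm), auc = ra$auc)
    rocs[[sp$iteration]] <- ra$roc
  }
  report <- aggregate_metrics(iter_metrics, rocs)
  list(report = report, records = records, splits = splits,
       config = list(variant = variant, size = size, n_iter = n_iter,
                     ratio = ratio, seed = seed, contrast = contrast,
                     base_width = base_width))
}

#' Write per-iteration and aggregate metrics as CSV
#'
#' @param report a `metrics_report`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_metrics_csv <- function(report, dir) {
  stopifnot(inherits(report, "metrics_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$per_iteration,
                   file.path(dir, "metrics_per_iteration.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "metrics_summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$mean_roc)) {
    utils::write.csv(report$mean_roc, file.path(dir, "roc_mean.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Plot the aggregated ROC curve
#'
#' Per-iteration curves dashed, the vertically averaged curve solid, and
#' a shaded +/- 1 SD band.
#'
#' @param report a `metrics_report` with ROC data.
#' @param rocs optional list of the per-iteration ROC data.frames.
#' @param path optional PNG output path; plots to the active device when
#'   `NULL`.
#' @return `path` or `NULL`, invisibly.
#' @importFrom grDevices png dev.off adjustcolor
#' @importFrom graphics polygon lines abline legend
#' @export
plot_mean_roc <- function(report, rocs = NULL, path = NULL) {
  stopifnot(inherits(report, "metrics_report"), !is.null(report$mean_roc))
  if (!is.null(path)) {
    grDevices::png(path, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  mr <- report$mean_roc
  auc_row <- report$summary[report$summary$metric == "auc", ]
  plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("Mean ROC (AUC %s)",
                      if (nrow(auc_row)) auc_row$formatted else ""))
  graphics::polygon(c(mr$fpr, rev(mr$fpr)), c(mr$tpr_lo, rev(mr$tpr_hi)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  if (!is.null(rocs)) {
    for (r in rocs) graphics::lines(r$fpr, r$tpr, lty = 2, col = "steelblue")
  }
  graphics::lines(mr$fpr, mr$tpr_mean, lwd = 2)
  graphics::abline(0, 1, lty = 3, col = "grey40")
  invisible(path)
}
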