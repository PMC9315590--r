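# Monte Carlo cross-validation, classification metrics, and ROC/AUC
# aggregation with mean +/- SD reporting.

#' Monte Carlo cross-validation split plans
#'
#' `n_iter` independent random train/test splits with
#' `|train| = ceil(ratio * n)` (65/27 for the 92-patient design at 70/30).
#' Splits are stratified by class via largest-remainder allocation so both
#' classes appear on each side; a split that still drops a class is
#' redrawn (error after 100 attempts).
#'
#' @param ids vector of example identifiers.
#' @param labels class label per id (used for stratification; pass `NULL`
#'   to disable stratification).
#' @param ratio training fraction, in (0, 1).
#' @param n_iter number of Monte Carlo iterations.
#' @param seed RNG seed; plans are reproducible.
#' @return List of `n_iter` plans, each `list(iteration, train, test)`.
#' @export
mc_splits <- function(ids, labels = NULL, ratio = 0.7, n_iter = 5, seed = 1) {
  n <- length(ids)
  stopifnot(n >= 4, ratio > 0, ratio < 1)
  n_train <- as.integer(ceiling(ratio * n))
  if (n_train >= n) stop("ratio leaves an empty test set")
  withr::with_seed(seed, {
    lapply(seq_len(n_iter), function(it) {
      for (attempt in seq_len(100)) {
        if (is.null(labels)) {
          tr <- sample(ids, n_train)
        } else {
          # largest-remainder allocation of the train quota across classes
          cls <- split(ids, labels)
          quota <- vapply(cls, length, integer(1)) * ratio
          base <- floor(quota)
          rem <- n_train - sum(base)
          extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
          base[extra] <- base[extra] + 1
          tr <- unlist(lapply(seq_along(cls), function(k) {
            sample(cls[[k]], base[k])
          }), use.names = FALSE)
        }
        te <- setdiff(ids, tr)
        if (is.null(labels)) return(list(iteration = it, train = tr, test = te))
        lt <- labels[match(tr, ids)]; le <- labels[match(te, ids)]
        # both classes must appear in training; the test set too, except in
        # the degenerate single-example-test case where it is impossible
        if (length(unique(lt)) > 1 &&
            (length(te) < 2 || length(unique(le)) > 1)) {
          return(list(iteration = it, train = tr, test = te))
        }
      }
      stop("could not draw a split containing both classes in train and test")
    })
  })
}

#' Confusion counts for a binary classifier
#'
#' @param truth,predicted label vectors of equal length.
#' @param positive_class the label counted as positive (default `"good"`
#'   collateral circulation).
#' @return Named integer vector `(tp, fp, tn, fn)`.
#' @export
confusion <- function(truth, predicted, positive_class = "good") {
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth == positive_class & predicted == positive_class)
  fp <- sum(truth != positive_class & predicted == positive_class)
  tn <- sum(truth != positive_class & predicted != positive_class)
  fn <- sum(truth == positive_class & predicted != positive_class)
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' accuracy = (tp + tn) / (tp + tn + fp + fn); precision = tp / (tp + fp);
#' recall = tp / (tp + fn); F1 = 2 * precision * recall /
#' (precision + recall). A metric whose denominator is zero is undefined
#' and reported as `NA`.
#'
#' @param counts named vector from [confusion()].
#' @return Named numeric vector `(accuracy, precision, recall, f1)`.
#' @export
metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  c(accuracy = (tp + tn) / total, precision = precision,
    recall = recall, f1 = f1)
}

#' ROC curve and AUC from scores
#'
#' Thresholds sweep the distinct scores in descending order (ties
#' grouped); the AUC is the trapezoidal area under the resulting curve,
#' which equals the Mann-Whitney pairwise-concordance statistic.
#'
#' @param scores numeric score per example (probability of the positive
#'   class).
#' @param truth label per example; both classes must be present.
#' @param positive_class label treated as positive.
#' @return List with `roc` (data.frame of `fpr`, `tpr` including the (0,0)
#'   and (1,1) endpoints) and `auc`.
#' @export
roc_auc <- function(scores, truth, positive_class = "good") {
  stopifnot(length(scores) == length(truth))
  pos <- truth == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(th) sum(scores >= th & pos) / n_pos, numeric(1))
  fpr <- vapply(thr, function(th) sum(scores >= th & !pos) / n_neg, numeric(1))
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Aggregate per-iteration metrics and ROC curves
#'
#' Mean and sample (n - 1) standard deviation per metric, reported
#' "mean +/- sd" as is conventional for cross-validated performance, and
#' the vertically averaged ROC: per-iteration curves are linearly
#' interpolated onto a common false-positive-rate grid and averaged, with
#' a +/- 1 SD band clipped to [0, 1].
#'
#' @param iteration_metrics list (or matrix rows) of named metric vectors,
#'   one per iteration.
#' @param rocs list of per-iteration ROC data.frames from [roc_auc()].
#' @param fpr_grid common false-positive-rate grid for vertical averaging.
#' @return A `metrics_report`: `per_iteration` (data.frame), `summary`
#'   (data.frame with mean, sd, and a formatted `mean +/- sd` string) and
#'   `mean_roc` (data.frame with `fpr`, `tpr_mean`, `tpr_lo`, `tpr_hi`).
#' @export
aggregate_metrics <- function(iteration_metrics, rocs = NULL,
                              fpr_grid = seq(0, 1, by = 0.01)) {
  if (length(iteration_metrics) < 2) stop("need at least 2 iterations")
  per_iter <- do.call(rbind, lapply(iteration_metrics, function(m) {
    as.data.frame(as.list(m))
  }))
  means <- vapply(per_iter, mean, numeric(1), na.rm = TRUE)
  sds <- vapply(per_iter, stats::sd, numeric(1), na.rm = TRUE)
  summary <- data.frame(metric = names(means), mean = unname(means),
                        sd = unname(sds),
                        formatted = sprintf("%.3f ± %.3f", means, sds))
  mean_roc <- NULL
  if (!is.null(rocs)) {
    tprs <- vapply(rocs, function(r) {
      stats::approx(r$fpr, r$tpr, xout = fpr_grid, ties = max, rule = 2)$y
    }, numeric(length(fpr_grid)))
    mu <- rowMeans(tprs)
    sdv <- apply(tprs, 1, stats::sd)
    mean_roc <- data.frame(fpr = fpr_grid, tpr_mean = mu,
                           tpr_lo = pmax(mu - sdv, 0),
                           tpr_hi = pmin(mu + sdv, 1))
  }
  structure(list(per_iteration = per_iter, summary = summary,
                 mean_roc = mean_roc, rocs = rocs, n_iter = nrow(per_iter)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", x$n_iter, " Monte Carlo iterations\n", sep = "")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-10s %s\n", x$summary$metric[i], x$summary$formatted[i]))
  }
  invisible(x)
}
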