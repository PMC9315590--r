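# R interface to the residual-network classifiers: a single-input model
# consuming the stitched four-phase montage, and a multi-input model with
# four identical per-phase branches fused by probability averaging.

.classes <- c("good", "poor")  # class index 0 = good (positive class)
.phases <- c("arterial", "arteriovenous", "venous", "late_venous")

#' Classifier configuration
#'
#' The residual architecture is fixed at four stages of (3, 4, 6, 3)
#' two-convolution blocks behind a 3x3 convolution stem and 3x3 max
#' pooling; channel widths are `base_width * (1, 2, 4, 8)` (the
#' 64-channel-base family at `base_width = 64`, smaller for desk-scale
#' work). Training uses Adam at learning rate 1e-4 with batch size 16,
#' capped at ten epochs with early stopping once the epoch-mean loss stops
#' decreasing.
#'
#' @param variant `"single"` (one network on the 2x2 montage) or
#'   `"multi"` (four identical branches, one per phase image, fused by
#'   averaging the class probabilities).
#' @param input_side input image side in pixels: the montage side for
#'   `"single"`, the per-phase image side for `"multi"`.
#' @param base_width channels of the first stage.
#' @param learning_rate,batch_size Adam step size and minibatch size.
#' @param max_epochs training epoch cap.
#' @param patience consecutive epochs without an improvement greater than
#'   `min_delta` in epoch-mean loss before training stops.
#' @param min_delta minimum loss improvement that counts as progress.
#' @param seed weight-initialisation / shuffling seed.
#' @param branch_weights fusion weights of the four branches (`"multi"`
#'   only); uniform by default.
#' @param pretrained reserved hook for externally supplied initial
#'   weights; the default is seeded random initialisation.
#' @return A `network_config` list.
#' @export
network_config <- function(variant = c("single", "multi"), input_side = 128,
                           base_width = 8, learning_rate = 1e-4,
                           batch_size = 16, max_epochs = 10, patience = 2,
                           min_delta = 1e-4, seed = 1,
                           branch_weights = rep(0.25, 4),
                           pretrained = FALSE) {
  variant <- match.arg(variant)
  stopifnot(learning_rate > 0, batch_size >= 2, max_epochs >= 1,
            input_side >= 16, length(branch_weights) == 4,
            abs(sum(branch_weights) - 1) < 1e-8)
  structure(list(variant = variant, input_side = as.integer(input_side),
                 blocks_per_stage = c(3L, 4L, 6L, 3L),
                 base_width = as.integer(base_width),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 seed = as.integer(seed), branch_weights = branch_weights,
                 pretrained = isTRUE(pretrained)),
            class = "network_config")
}

#' Build an untrained classifier
#'
#' @param config a [network_config()].
#' @param init_params optional externally supplied initial weights (the
#'   pre-training hook); seeded random initialisation otherwise.
#' @return A `collat_model` with untrained weights.
#' @export
build_classifier <- function(config, init_params = NULL) {
  stopifnot(inherits(config, "network_config"))
  if (config$pretrained && is.null(init_params)) {
    stop("pretrained = TRUE requires init_params with externally trained weights")
  }
  if (config$variant == "single") {
    params <- if (!is.null(init_params)) init_params else
      cpp_resnet_init(config$input_side, 1L, config$base_width, config$seed)
    structure(list(config = config, params = params, trained = FALSE,
                   loss_history = NULL), class = "collat_model")
  } else {
    branches <- if (!is.null(init_params)) init_params else
      lapply(0:3, function(k) {
        cpp_resnet_init(config$input_side, 1L, config$base_width,
                        config$seed + k)
      })
    names(branches) <- .phases
    structure(list(config = config, branches = branches, trained = FALSE,
                   loss_history = NULL), class = c("collat_multi_model",
                                                   "collat_model"))
  }
}

# Coerce a list of equally sized matrices to an (H, W, n) array.
.stack_images <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  stopifnot(is.list(x), length(x) >= 1)
  d <- dim(x[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(x)))
  for (i in seq_along(x)) arr[, , i] <- unclass(x[[i]])
  arr
}

.encode_labels <- function(y) {
  y <- as.character(y)
  if (!all(y %in% .classes)) stop("labels must be 'good' or 'poor'")
  as.integer(y == "poor")  # class index: good = 0, poor = 1
}

#' Train a classifier
#'
#' Minimises the two-class cross-entropy with Adam (learning rate, batch
#' size, epoch cap, and early-stopping patience from the model's config).
#' The multi-input variant trains its four phase branches independently on
#' their own phase images; fusion happens at prediction time by averaging
#' the branch probabilities.
#'
#' @param model an untrained (or previously trained) `collat_model`.
#' @param x for `"single"`: montages as an (H, W, n) array or list of
#'   matrices. For `"multi"`: a named list with one (H, W, n) array (or
#'   list of matrices) per phase (`arterial`, `arteriovenous`, `venous`,
#'   `late_venous`).
#' @param y labels, `"good"`/`"poor"`, length n; both classes with at
#'   least 2 examples each must be present.
#' @return The trained model with `loss_history` (per-epoch mean training
#'   loss; one vector per branch for the multi-input variant).
#' @export
train_classifier <- function(model, x, y) {
  stopifnot(inherits(model, "collat_model"))
  cfg <- model$config
  yi <- .encode_labels(y)
  if (min(table(factor(yi, levels = 0:1))) < 2) {
    stop("need at least 2 training examples per class")
  }
  if (inherits(model, "collat_multi_model")) {
    stopifnot(is.list(x), all(.phases %in% names(x)))
    hist <- list()
    for (k in seq_along(.phases)) {
      ph <- .phases[k]
      arr <- .stack_images(x[[ph]])
      fit <- cpp_resnet_train(model$branches[[ph]], as.numeric(arr),
                              as.integer(dim(arr)), yi,
                              cfg$learning_rate, cfg$batch_size,
                              cfg$max_epochs, cfg$patience, cfg$min_delta,
                              cfg$seed + 1000L * k)
      model$branches[[ph]] <- fit$params
      hist[[ph]] <- fit$loss_history
    }
    model$loss_history <- hist
  } else {
    arr <- .stack_images(x)
    fit <- cpp_resnet_train(model$params, as.numeric(arr),
                            as.integer(dim(arr)), yi,
                            cfg$learning_rate, cfg$batch_size,
                            cfg$max_epochs, cfg$patience, cfg$min_delta,
                            cfg$seed)
    model$params <- fit$params
    model$loss_history <- fit$loss_history
  }
  model$trained <- TRUE
  model
}

# Probability matrix (n x 2, columns p_good, p_poor) for one network.
.predict_single <- function(params, x) {
  arr <- .stack_images(x)
  p <- cpp_resnet_predict(params, as.numeric(arr), as.integer(dim(arr)))
  colnames(p) <- c("p_good", "p_poor")
  p
}

#' Average branch probabilities (late fusion)
#'
#' The fused per-class probability is the (weighted) arithmetic mean of
#' the branch probabilities; with probabilities summing to 1 per branch
#' and weights summing to 1, the fused pair again sums to 1.
#'
#' @param branch_probs list of n x 2 probability matrices, one per branch.
#' @param weights fusion weights, one per branch, summing to 1.
#' @return An n x 2 matrix with columns `p_good`, `p_poor`.
#' @export
average_probabilities <- function(branch_probs, weights = NULL) {
  k <- length(branch_probs)
  if (is.null(weights)) weights <- rep(1 / k, k)
  stopifnot(length(weights) == k, abs(sum(weights) - 1) < 1e-8)
  out <- Reduce(`+`, Map(function(p, w) w * p, branch_probs, weights))
  colnames(out) <- c("p_good", "p_poor")
  out
}

#' Forward pass of the multi-input model
#'
#' Runs the four phase images through their branches and averages the
#' class probabilities.
#'
#' @param model a trained `collat_multi_model`.
#' @param images named list with one (H, W, n) array (or list of
#'   matrices) per phase.
#' @return n x 2 matrix of fused probabilities.
#' @export
forward_multi <- function(model, images) {
  stopifnot(inherits(model, "collat_multi_model"),
            all(.phases %in% names(images)))
  probs <- lapply(.phases, function(ph) {
    .predict_single(model$branches[[ph]], images[[ph]])
  })
  average_probabilities(probs, model$config$branch_weights)
}

#' Predict collateral class
#'
#' The class with the larger probability wins; an exact tie predicts
#' `"poor"` (the conservative call: a flagged-poor patient is reviewed for
#' intervention).
#'
#' @param object a trained `collat_model`.
#' @param x montages (single variant) or named per-phase image list
#'   (multi variant), as in [train_classifier()].
#' @param ... unused.
#' @return Data.frame with `p_good`, `p_poor`, `label`.
#' @export
predict.collat_model <- function(object, x, ...) {
  probs <- if (inherits(object, "collat_multi_model")) {
    forward_multi(object, x)
  } else {
    .predict_single(object$params, x)
  }
  label <- ifelse(probs[, "p_good"] > probs[, "p_poor"], "good", "poor")
  data.frame(p_good = probs[, "p_good"], p_poor = probs[, "p_poor"],
             label = label, stringsAsFactors = FALSE)
}

#' @export
print.collat_model <- function(x, ...) {
  cat("<collat_model> ", x$config$variant, "-input, side ",
      x$config$input_side, ", base width ", x$config$base_width, ", ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Residual-block forward pass (evaluation mode)
#'
#' Direct access to one residual block, used to verify the skip wiring:
#' with all convolution weights zero and identity batch-norm statistics
#' the block must reduce to `relu(x)`.
#'
#' @param x input feature map, an (H, W, C) array.
#' @param c1,c2 lists with `W` (cout x cin*k*k), `gamma`, `beta`,
#'   `rmean`, `rvar` for the two convolutions.
#' @param stride stride of the first convolution (2 at stage entry).
#' @param proj optional projection (1x1 convolution) parameter list for
#'   the skip path when shape changes.
#' @return The block output as an (Ho, Wo, Cout) array.
#' @export
residual_block_forward <- function(x, c1, c2, stride = 1, proj = NULL) {
  stopifnot(length(dim(x)) == 3)
  cpp_block_forward(as.numeric(x), as.integer(dim(x)), c1, c2,
                    as.integer(stride), proj)
}

#' Save / load a trained model
#'
#' @param model a `collat_model`.
#' @param path file path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
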