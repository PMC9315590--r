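# Toy image set: class decided by a bright top-left quadrant.
toy_images <- function(n, side = 32, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("good", "poor"), length.out = n)
    X <- array(0, c(side, side, n))
    for (i in seq_len(n)) {
      img <- matrix(runif(side * side, 0, 0.2), side)
      if (y[i] == "good") {
        q <- seq_len(side / 2)
        img[q, q] <- img[q, q] + 0.6
      }
      X[, , i] <- img
    }
    list(x = X, y = y)
  })
}

small_cfg <- function(...) {
  network_config("single", input_side = 32, base_width = 4, seed = 2, ...)
}

test_that("forward pass produces valid probability pairs", {
  m <- build_classifier(small_cfg())
  d <- toy_images(6)
  p <- predict(m, d$x)
  expect_true(all(abs(p$p_good + p$p_poor - 1) < 1e-6))
  expect_true(all(p$p_good >= 0 & p$p_good <= 1))
})

test_that("residual block reduces to its skip path under zero weights", {
  withr::with_seed(3, {
    C <- 3; H <- 8; W <- 8
    x <- array(abs(rnorm(H * W * C)), c(H, W, C))  # non-negative input
    zero_conv <- function(cin, cout, k) {
      list(W = matrix(0, cout, cin * k * k), gamma = rep(1, cout),
           beta = rep(0, cout), rmean = rep(0, cout), rvar = rep(1, cout))
    }
    out <- residual_block_forward(x, zero_conv(C, C, 3), zero_conv(C, C, 3),
                                  stride = 1)
    # residual branch contributes 0, so the block is relu(x) = x here
    expect_equal(out, x, tolerance = 1e-6)

    # non-zero branch: output differs from the input (wiring is additive,
    # not a replacement)
    c1 <- zero_conv(C, C, 3); c1$W[1, 1] <- 1
    out2 <- residual_block_forward(x, c1, zero_conv(C, C, 3), stride = 1)
    expect_equal(out2, x, tolerance = 1e-6)  # second conv still zero
    c2 <- zero_conv(C, C, 3); c2$beta <- rep(0.5, C)
    out3 <- residual_block_forward(x, c1, c2, stride = 1)
    expect_equal(out3, x + 0.5, tolerance = 1e-6)
  })
})

test_that("training reduces the loss on separable data, deterministically", {
  d <- toy_images(20)
  m <- train_classifier(build_classifier(small_cfg(max_epochs = 6)), d$x, d$y)
  expect_true(m$trained)
  expect_gt(length(m$loss_history), 0)
  expect_lt(m$loss_history[length(m$loss_history)], m$loss_history[1])

  m2 <- train_classifier(build_classifier(small_cfg(max_epochs = 6)), d$x, d$y)
  expect_identical(m$loss_history, m2$loss_history)
  p1 <- predict(m, d$x); p2 <- predict(m2, d$x)
  expect_identical(p1, p2)

  expect_error(train_classifier(build_classifier(small_cfg()),
                                d$x[, , d$y == "good"],
                                d$y[d$y == "good"]),
               "per class")
})

test_that("early stopping halts a stalled optimisation before the epoch cap", {
  d <- toy_images(12)
  # learning rate ~0: the epoch-mean loss cannot improve, so training must
  # stop after 1 + patience epochs
  m <- train_classifier(
    build_classifier(small_cfg(learning_rate = 1e-12, max_epochs = 10,
                               patience = 2)),
    d$x, d$y)
  expect_identical(length(m$loss_history), 3L)
})

test_that("prediction is batch-packing invariant and ties go to poor", {
  d <- toy_images(5)
  m <- build_classifier(small_cfg())
  batched <- predict(m, d$x)
  single <- do.call(rbind, lapply(seq_len(5), function(i) {
    predict(m, d$x[, , i, drop = FALSE])
  }))
  expect_equal(batched$p_good, single$p_good, tolerance = 1e-5)

  # zero fully-connected weights force logits (0, 0) -> probabilities
  # (0.5, 0.5) -> the conservative tie rule predicts poor
  m0 <- m
  m0$params$fc_W[] <- 0
  m0$params$fc_b[] <- 0
  p0 <- predict(m0, d$x)
  expect_true(all(abs(p0$p_good - 0.5) < 1e-12))
  expect_true(all(p0$label == "poor"))
})

test_that("multi-input fusion averages branch probabilities", {
  probs <- list(
    matrix(c(0.8, 0.2), 1), matrix(c(0.6, 0.4), 1),
    matrix(c(0.4, 0.6), 1), matrix(c(1.0, 0.0), 1))
  fused <- average_probabilities(probs)
  expect_equal(unname(fused[1, "p_good"]), 0.7)
  expect_equal(unname(sum(fused[1, ])), 1)
  # degenerate all-tied case stays a tie
  tied <- average_probabilities(rep(list(matrix(c(0.5, 0.5), 1)), 4))
  expect_equal(unname(tied[1, 1]), 0.5)

  # a trained multi model produces valid fused probabilities
  d <- toy_images(8, side = 32)
  phases <- list(arterial = d$x, arteriovenous = d$x, venous = d$x,
                 late_venous = d$x)
  cfg <- network_config("multi", input_side = 32, base_width = 4,
                        max_epochs = 1, seed = 5)
  mm <- train_classifier(build_classifier(cfg), phases, d$y)
  pm <- predict(mm, phases)
  expect_true(all(abs(pm$p_good + pm$p_poor - 1) < 1e-6))
  expect_length(mm$loss_history, 4)
})

test_that("pretrained hook requires external weights", {
  expect_error(build_classifier(small_cfg(pretrained = TRUE)),
               "init_params")
})
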