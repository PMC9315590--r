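test_that("TDC extraction subtracts the baseline over the ROI", {
  s <- tiny_study("good", seed = 2, noise_sd = 0)
  gt <- s$ground_truth

  # contrast-free parenchyma: curve is identically ~0
  brain <- which(brain_mask(dim(s$ncct)))
  quiet <- setdiff(brain, c(gt$artery_roi, gt$vein_roi))
  changed <- Reduce(`|`, lapply(s$frames, function(f) abs(f - s$ncct) > 1e-9))
  quiet <- setdiff(quiet, which(changed))[1:20]
  curve0 <- extract_tdc(s, quiet, "artery")
  expect_true(all(abs(curve0$values) < 1e-9))

  # noiseless arterial ROI reproduces the generating gamma-variate exactly
  art <- extract_tdc(s, gt$artery_roi, "artery")
  expect_equal(art$values, oracle_gv(art$times, gt$arterial), tolerance = 1e-8)
  ven <- extract_tdc(s, gt$vein_roi, "vein")
  expect_equal(ven$values, oracle_gv(ven$times, gt$venous), tolerance = 1e-8)

  # single-voxel ROI equals that voxel's subtracted series
  vx <- gt$artery_roi[1]
  one <- extract_tdc(s, vx, "artery")
  expect_equal(one$values,
               vapply(s$frames, function(f) f[vx] - s$ncct[vx], numeric(1)))

  expect_error(extract_tdc(s, integer(0)), "at least one voxel")
  expect_error(extract_tdc(s, 10^9), "bounds")
})

test_that("curve QC counts prominent peaks and flags boundary maxima", {
  tt <- seq(11, 60, by = 2)
  p1 <- list(t0 = 10, alpha = 3, beta = 3, A = 100)
  clean <- tdc(tt, oracle_gv(tt, p1), "artery")
  q <- qc_curve(clean)
  expect_identical(q$n_peaks, 1L)
  expect_true(q$is_bell_shaped)
  expect_true(q$starts_after_zero)

  # two well-separated boluses: two prominent peaks, rejected
  p2 <- list(t0 = 38, alpha = 3, beta = 2, A = 60)
  double <- tdc(tt, oracle_gv(tt, p1) + oracle_gv(tt, p2), "artery")
  qd <- qc_curve(double)
  expect_identical(qd$n_peaks, oracle_n_peaks(double$values))
  expect_identical(qd$n_peaks, 2L)
  expect_false(qd$is_bell_shaped)

  # monotone curve: maximum at the boundary, not bell-shaped
  mono <- tdc(tt, seq_along(tt), "artery")
  expect_false(qc_curve(mono)$is_bell_shaped)

  # all-zero curve
  zero <- tdc(tt, rep(0, length(tt)), "artery")
  qz <- qc_curve(zero)
  expect_identical(qz$n_peaks, 0L)
  expect_false(qz$is_bell_shaped)

  # low-prominence ripple is not a second peak
  v <- oracle_gv(tt, p1)
  v[20] <- v[20] + 0.05 * max(v)
  expect_identical(qc_curve(tdc(tt, v, "artery"))$n_peaks, 1L)
})

test_that("peak finding takes the earliest global-maximum sample", {
  cv <- tdc(c(11, 13, 15, 17, 19), c(0, 1, 5, 2, 0), "artery")
  pk <- find_peak(cv)
  expect_equal(pk$time, 15)
  expect_identical(pk$frame_index, 3L)

  flat <- tdc(c(11, 13, 15, 17), c(0, 5, 5, 0), "artery")
  expect_identical(find_peak(flat, check = FALSE)$frame_index, 2L)

  mono <- tdc(c(11, 13, 15), c(1, 2, 3), "artery")
  expect_error(find_peak(mono), "bell")
})

test_that("artery-vein intersection interpolates then snaps after the arterial peak", {
  tt <- c(17, 19, 21, 23, 25, 27)
  art <- tdc(tt, c(2, 6, 10, 4, 2, 1), "artery")
  ven <- tdc(tt, c(0, 2, 6, 8, 9, 8), "vein")
  res <- find_av_intersection(art, ven, check = FALSE)
  # difference 4 -> -4 crosses zero at 21 + 2 * (4/8) = 22; frames at the
  # arterial peak are excluded, so 22 snaps to frame 23
  expect_equal(res$t_star, 22)
  expect_equal(res$time, 23)
  expect_identical(res$frame_index, 4L)
  expect_false(res$flagged)

  # crossing exactly at an acquired frame
  art2 <- tdc(tt, c(2, 6, 10, 5, 2, 1), "artery")
  ven2 <- tdc(tt, c(0, 1, 3, 5, 9, 8), "vein")
  res2 <- find_av_intersection(art2, ven2, check = FALSE)
  expect_equal(res2$t_star, 23)
  expect_equal(res2$time, 23)

  # arterial always above venous in the window: fallback, flagged
  art3 <- tdc(tt, c(2, 6, 10, 9, 8, 7), "artery")
  ven3 <- tdc(tt, c(0, 1, 2, 3, 4, 5), "vein")
  res3 <- find_av_intersection(art3, ven3, check = FALSE)
  expect_true(res3$flagged)
  d <- art3$values - ven3$values
  idx <- which(tt > 21 & tt <= 27)
  expect_identical(res3$frame_index, idx[which.min(abs(d[idx]))])

  expect_error(find_av_intersection(art, art, check = FALSE), "degenerate|peak")
})

test_that("late-venous finder applies the plateau value + slope rule", {
  tt <- c(40, 45, 50, 55, 60, 65)
  ven <- tdc(tt, c(0, 8, 10, 6, 4.8, 4.6), "vein")
  res <- find_late_venous(ven, plateau_frac = 0.5, slope_tol = 0.2,
                          check = FALSE)
  expect_equal(res$time, 60)  # value 4.8 <= 5 and |slope| = 0.04 <= 0.2
  expect_false(res$flagged)

  # never drops below the plateau fraction: last frame, flagged
  high <- tdc(tt, c(0, 8, 10, 9, 8.5, 8.2), "vein")
  res2 <- find_late_venous(high, check = FALSE)
  expect_identical(res2$frame_index, length(tt))
  expect_true(res2$flagged)

  # peak at the last frame is rejected
  rising <- tdc(tt, c(0, 1, 2, 3, 4, 9), "vein")
  expect_error(find_late_venous(rising, check = FALSE), "last frame")

  # steep clean decay: agrees with a brute-force scan of the same rule
  p <- list(t0 = 18, alpha = 6, beta = 4, A = 120)
  tt2 <- contrast_times(make_protocol())
  v <- oracle_gv(tt2, p)
  cv <- tdc(tt2, v, "vein")
  res3 <- find_late_venous(cv, plateau_frac = 0.5, slope_tol = 6)
  pk_i <- which.max(v)
  scan <- NA
  for (i in seq(pk_i + 1, length(tt2))) {
    sl <- if (i < length(tt2)) (v[i + 1] - v[i]) / (tt2[i + 1] - tt2[i])
          else (v[i] - v[i - 1]) / (tt2[i] - tt2[i - 1])
    if (v[i] <= 0.5 * v[pk_i] && abs(sl) <= 6) { scan <- i; break }
  }
  expect_identical(res3$frame_index, scan)
})

test_that("landmark composition enforces phase ordering and shift-equivariance", {
  s <- tiny_study("good", seed = 21, noise_sd = 0)
  gt <- s$ground_truth
  art <- extract_tdc(s, gt$artery_roi, "artery")
  ven <- extract_tdc(s, gt$vein_roi, "vein")
  lm <- landmarks(art, ven)
  with(as.list(lm$times), {
    expect_lt(arterial, arteriovenous)
    expect_lte(arteriovenous, venous)
    expect_lt(venous, late_venous)
  })
  expect_true(lm$times[["arterial"]] >= 11 && lm$times[["arterial"]] <= 36)
  expect_gte(lm$times[["venous"]], 40)

  # swapped curves: venous peak precedes arterial peak -> rejected
  art_sw <- tdc(ven$times, ven$values, "artery")
  ven_sw <- tdc(art$times, art$values, "vein")
  expect_error(landmarks(art_sw, ven_sw), "mis-selected|ordering")

  # translating both curves (same grid) translates every landmark
  shift <- 2
  art2 <- tdc(art$times + shift, art$values, "artery")
  ven2 <- tdc(ven$times + shift, ven$values, "vein")
  lm2 <- landmarks(art2, ven2)
  expect_equal(lm2$times, lm$times + shift)
  expect_identical(lm2$frame_index, lm$frame_index)
})

test_that("landmark finders agree with exhaustive frame scans on random curves", {
  tt <- contrast_times(make_protocol())
  withr::with_seed(7, {
    for (i in 1:15) {
      art_p <- list(t0 = runif(1, 9, 12), alpha = runif(1, 2.6, 3.4),
                    beta = runif(1, 2.3, 3.1), A = runif(1, 170, 240))
      ven_p <- list(t0 = art_p$t0 + runif(1, 9, 10.5),
                    alpha = runif(1, 6, 6.3), beta = runif(1, 3.85, 4.05),
                    A = runif(1, 90, 130))
      a <- oracle_gv(tt, art_p); v <- oracle_gv(tt, ven_p)
      art <- tdc(tt, a, "artery"); ven <- tdc(tt, v, "vein")

      expect_identical(find_peak(art)$frame_index, which.max(a))
      expect_identical(find_peak(ven)$frame_index, which.max(v))

      lm <- landmarks(art, ven)
      # exhaustive scan for the first post-arterial-peak frame where the
      # interpolated difference has crossed below zero
      ia <- which.max(a); iv <- which.max(v)
      d <- a - v
      cross <- NA_real_
      for (k in seq_len(length(tt) - 1)) {
        if (tt[k + 1] <= tt[ia] || tt[k] > tt[iv]) next
        if (d[k] >= 0 && d[k + 1] < 0) {
          cross <- tt[k] + (tt[k + 1] - tt[k]) * d[k] / (d[k] - d[k + 1])
          break
        }
      }
      expect_false(is.na(cross))
      in_win <- tt > tt[ia] & tt <= tt[iv]
      snap <- tt[in_win][which.min(abs(tt[in_win] - cross))]
      expect_equal(lm$times[["arteriovenous"]], snap)
    }
  })
})
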