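test_that("grade assignment follows the five-level collateral scale", {
  expect_identical(assign_grade(c(0, 0, 0, 0)), 0L)
  expect_identical(assign_grade(c(0.95, 1, 1, 1)), 4L)
  expect_identical(assign_grade(c(0.2, 0.3, 0.5, 0.95)), 3L)
  expect_identical(assign_grade(c(0.2, 0.3, 0.5, 0.6)), 2L)
  expect_identical(assign_grade(c(0.02, 0.05, 0.3, 0.6)), 1L)
  # complete filling only in the late venous phase is grade 3 even with
  # little early filling
  expect_identical(assign_grade(c(0, 0, 0, 0.95)), 3L)
  expect_error(assign_grade(c(0.5, 0.4, 0.6, 0.7)), "non-decreasing")
})

test_that("grade assignment is monotone in the filling fractions", {
  withr::with_seed(11, {
    for (i in 1:200) {
      f <- sort(runif(4))
      g <- pmin(f + sort(runif(4, 0, 0.3)), 1)
      g <- cummax(g)
      expect_gte(assign_grade(g), assign_grade(f))
    }
  })
})

test_that("study generation is deterministic and respects the label contract", {
  s1 <- tiny_study("good", seed = 5, noise_sd = 2)
  s2 <- tiny_study("good", seed = 5, noise_sd = 2)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$ncct, s2$ncct)
  expect_identical(s1$ground_truth, s2$ground_truth)

  expect_length(s1$frames, length(s1$protocol) - 1)
  expect_true(all(vapply(s1$frames, function(f) identical(dim(f), dim(s1$ncct)),
                         logical(1))))
  expect_error(generate_study("good", size = c(4, 32, 32)), "at least")
  expect_error(generate_study("maybe"), "arg")

  for (seed in 1:6) {
    g <- generate_study(
      sample(c("good", "poor"), 1), size = c(8, 32, 32), seed = seed)
    expect_identical(g$label == "good", g$grade >= 3L)
    expect_true(all(diff(g$ground_truth$fill) >= -1e-9))
    expect_identical(assign_grade(g$ground_truth$fill), g$grade)
  }
})

test_that("contrast is confined to vessels: NCCT equals contrast frames elsewhere", {
  s <- tiny_study("good", seed = 3, noise_sd = 0)
  gt <- s$ground_truth
  vessel_or_bone <- rep(FALSE, length(s$ncct))
  # any voxel that changes in any frame must be a vessel; bone stays fixed
  changed <- Reduce(`|`, lapply(s$frames, function(f) abs(f - s$ncct) > 1e-9))
  expect_true(all(s$ncct[changed] < 150))        # never bone
  expect_true(all(brain_mask(dim(s$ncct))[changed]))  # inside the brain
  # the arterial ROI itself must carry the arterial curve
  expect_true(all(changed[gt$artery_roi]))
})

test_that("poor studies show an arterial-phase filling deficit in the occluded territory", {
  # averaged over seeds: occluded-territory enhancement poor << good, and
  # poor occluded < its mirrored contralateral territory
  diffs <- vapply(1:10, function(seed) {
    sp <- tiny_study("poor", seed = seed, noise_sd = 2, contrast = "strong")
    sg <- tiny_study("good", seed = seed + 100, noise_sd = 2, contrast = "strong")
    m <- function(s) {
      tm <- territory_masks(dim(s$ncct), s$ground_truth$occluded_side)
      inp <- study_to_inputs(s)
      ps <- build_phase_set(s, inp$landmarks)
      c(occ = mean(ps$volumes$arterial[tm$occluded]),
        con = mean(ps$volumes$arterial[tm$contralateral]))
    }
    mp <- m(sp); mg <- m(sg)
    expect_lt(mp[["occ"]], mp[["con"]])  # deficit vs mirrored territory
    mg[["occ"]] - mp[["occ"]]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("cohort generation matches requested class sizes and is reproducible", {
  c1 <- generate_cohort(50, 42, seed = 9, keep_volumes = FALSE)
  expect_identical(nrow(c1$records), 92L)
  expect_identical(sum(c1$records$label == "good"), 50L)
  expect_identical(sum(c1$records$label == "poor"), 42L)
  c2 <- generate_cohort(50, 42, seed = 9, keep_volumes = FALSE)
  expect_identical(c1$records, c2$records)

  c3 <- generate_cohort(2, 2, seed = 1, keep_volumes = FALSE)
  expect_identical(nrow(c3$records), 4L)
  expect_error(generate_cohort(0, 5), "non-empty")
  expect_error(generate_cohort(2, 1), "at least 4")

  expect_true(all(c1$records$grade %in% 0:4))
  expect_identical(c1$records$label == "good", c1$records$grade >= 3L)
  expect_true(all(c1$records$onset_bin %in% c("<6h", "6-24h", ">24h")))
  expect_true(is.logical(c1$records$hemorrhagic_transformation))
})

test_that("studies round-trip through NIfTI + JSON on disk", {
  s <- tiny_study("poor", seed = 13, noise_sd = 1)
  dir <- withr::local_tempdir()
  write_study(s, dir)
  expect_true(file.exists(file.path(dir, "ncct.nii.gz")))
  r <- read_study(dir)
  expect_equal(r$ncct, s$ncct, tolerance = 1e-5)
  expect_identical(length(r$frames), length(s$frames))
  expect_equal(r$frames[[7]], s$frames[[7]], tolerance = 1e-5)
  expect_identical(r$grade, s$grade)
  expect_equal(r$ground_truth$fill, s$ground_truth$fill)
  tab <- file.path(dir, "cohort.csv")
  rec <- generate_cohort(2, 2, seed = 2, keep_volumes = FALSE)$records
  write_cohort_csv(rec, tab)
  expect_identical(read_cohort_csv(tab)$label, rec$label)
})
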