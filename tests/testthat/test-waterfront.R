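test_that("water classification follows the threshold rule", {
  p <- build_phantom(5, c(64, 64, 48), seed = 2)
  v <- optics_maps(p)$delta
  mask <- p$vessel_map
  expect_false(any(classify_water(volume_image(v, semantics = "delta"),
                                  volume_image(v, semantics = "delta"),
                                  mask, 1e-7)))
  # halfway threshold from the published class means
  expect_equal(halfway_threshold(5.11e-7, 0.97e-7), 2.07e-7)
  # noisy volumes at a class gap of 6 sd misclassify < 0.2% of voxels
  gap <- 5.1e-7
  w <- fill_state(p, fill_schedule(p$vessel_table), 1e8)   # fully wet
  u <- noisy_delta_volume(w, gap / 6, 11L)
  vd <- volume_image(optics_maps(p)$delta, semantics = "delta")
  water <- classify_water(u, vd, mask, gap / 2)
  truth <- w$labels == 2L
  err <- mean(water[mask > 0] != truth[mask > 0])
  expect_lt(err, 0.002)
})

test_that("thickness ratio matches constructed masks", {
  vessel <- array(FALSE, c(8, 6, 10)); vessel[3:5, 2:4, ] <- TRUE
  water <- vessel; water[, , 6:10] <- FALSE        # lower half filled
  R <- thickness_ratio(water, vessel, axis = 1L)
  expect_equal(dim(R), c(6, 10))
  expect_true(all(R[2:4, 1:5] == 1))
  expect_true(all(R[2:4, 6:10] == 0))
  expect_true(all(is.na(R[c(1, 5, 6), ])))
  expect_true(all(thickness_ratio(vessel, vessel)[2:4, ] == 1))
  expect_true(all(thickness_ratio(vessel & FALSE, vessel)[2:4, ] == 0))
})

test_that("front height follows the persistence rule (brute-force oracle)", {
  expect_equal(front_height(c(1, 1, 1, 0, 0, 0, 0), persistence = 3), 3)
  expect_equal(front_height(rep(0, 30)), 0)
  # a droplet above the front, beyond the persistence window, is ignored
  r <- c(rep(1, 10), rep(0, 25), 0.9, rep(0, 30))
  expect_equal(front_height(r, persistence = 20), 10)
  # a sub-persistence dip below the front does not pull the front down
  r2 <- c(rep(1, 5), 0, 0, rep(1, 5), rep(0, 40))
  expect_equal(front_height(r2, persistence = 20), 12)
  # randomised profiles against the brute-force scan
  for (trial in 1:25) {
    r <- withr::with_seed(trial, sample(c(0, 0.05, 0.2, 0.6, 1), 60, replace = TRUE))
    for (pers in c(1, 5, 20)) {
      expect_equal(front_height(r, 0.1, pers),
                   front_height_bruteforce(r, 0.1, pers))
    }
  }
  expect_error(front_height(rep(NA_real_, 5)), "undefined")
})

test_that("front fluctuations strictly above the persistence window are ignored", {
  base <- c(rep(1, 12), rep(0, 40))
  h0 <- front_height(base, persistence = 10)
  pert <- base; pert[30:52] <- withr::with_seed(4, runif(23))
  expect_equal(front_height(pert, persistence = 10), h0)
})

test_that("threshold sweep bounds bracket the nominal front height", {
  # sharp step: zero-width interval
  step <- c(rep(1, 15), rep(0, 40))
  b <- front_uncertainty(step, persistence = 10)
  expect_equal(unname(b[["high"]] - b[["low"]]), 0)
  # linear ramp R = 1 - z/L: crossings at 0.85 L and 0.95 L
  L <- 100
  ramp <- 1 - (0:(L - 1)) / L
  prof <- c(ramp, rep(0, 30))
  b2 <- front_uncertainty(prof, persistence = 20)
  expect_lt(abs(b2[["low"]] - 0.85 * L), 1.5)
  expect_lt(abs(b2[["high"]] - 0.95 * L), 1.5)
  # bounds bracket the 0.1-threshold height for random profiles
  for (trial in 1:10) {
    r <- withr::with_seed(100 + trial,
                          pmax(0, 1 - (0:79) / 50 + rnorm(80, 0, 0.1)))
    h <- front_height(r, 0.1, 10)
    b3 <- front_uncertainty(r, c(0.05, 0.15), 10)
    expect_gte(h, b3[["low"]]); expect_lte(h, b3[["high"]])
  }
})

test_that("vessel segmentation from the reference finds the true tubes", {
  p <- build_phantom(5, c(64, 64, 48), seed = 3)
  v <- noisy_delta_volume(p, 5.1e-7 / 20, 7L)
  labels <- segment_vessels(v)
  ids <- setdiff(unique(as.integer(labels)), 0L)
  expect_equal(length(ids), 5)
  # each segmented tube coincides with one true vessel (Jaccard > 0.6)
  for (id in ids) {
    tv <- as.integer(names(which.max(table(p$vessel_map[labels == id]))))
    inter <- sum(labels == id & p$vessel_map == tv)
    union <- sum(labels == id | p$vessel_map == tv)
    expect_gt(inter / union, 0.6)
  }
})

test_that("static timelines track a constant base-level front", {
  p <- build_phantom(3, c(48, 48, 40), seed = 8)
  v <- noisy_delta_volume(p, 5.1e-7 / 30, 5L)
  timeline <- lapply(1:3, function(i) noisy_delta_volume(p, 5.1e-7 / 30, 50L + i))
  labels <- segment_vessels(v)
  tr <- track_vessels(timeline, v, labels, halfway_threshold(5.1e-7, 0),
                      times = c(9, 18, 27), persistence = 10L)
  expect_true(all(tr$tracks$h == 0))
  expect_true(all(tr$monotone$monotone))
  # cohort summary equals direct recomputation from the stacked heights
  for (t in unique(tr$tracks$t)) {
    hs <- tr$tracks$h[tr$tracks$t == t]
    expect_equal(tr$cohort$median_h[tr$cohort$t == t], median(hs))
    expect_equal(tr$cohort$sd_h[tr$cohort$t == t], sd(hs))
  }
})
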