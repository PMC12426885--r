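# Alignment recovery on simulated flyscans against the reference volume.
# The textured slice scenario is shared with the dTV tests; offsets are in
# units of the 1 degree/projection angular step.

test_that("zero and injected offsets are recovered exactly on the grid", {
  sc <- slice_scenario()
  dyn0 <- simulate_scan(sc$wet, dynamic_protocol(n_projections = 180, seed = 6,
                                                 photons_per_pixel = 5000),
                        sc$geom)
  al0 <- estimate_angular_offset(retrieve_projections(dyn0), sc$v, seq(-5, 5))
  expect_equal(al0$estimate, 0)
  dyn3 <- simulate_scan(sc$wet, dynamic_protocol(n_projections = 180, seed = 7,
                                                 offset_deg = 3,
                                                 photons_per_pixel = 5000), sc$geom)
  al3 <- estimate_angular_offset(retrieve_projections(dyn3), sc$v, seq(-10, 10))
  expect_equal(al3$estimate, 3)
  expect_equal(nrow(al3$objective_curve), 21)
  # the objective at the truth beats every other grid point
  expect_equal(al3$objective_curve$candidate[
    which.min(al3$objective_curve$objective)], 3)
})

test_that("a half-step offset lands on a neighbouring candidate with a note", {
  sc <- slice_scenario()
  dyn <- simulate_scan(sc$wet, dynamic_protocol(n_projections = 180, seed = 8,
                                                offset_deg = 1.5,
                                                photons_per_pixel = 5000), sc$geom)
  al <- estimate_angular_offset(retrieve_projections(dyn), sc$v, seq(-5, 5))
  expect_true(al$estimate %in% c(1, 2))
  expect_true(any(grepl("sub-grid", al$notes)))
})

test_that("alignment is invariant to global intensity scaling", {
  sc <- slice_scenario()
  dyn <- simulate_scan(sc$wet, dynamic_protocol(n_projections = 180, seed = 7,
                                                offset_deg = 3), sc$geom)
  sino <- retrieve_projections(dyn)
  sino_scaled <- sino; sino_scaled$data <- sino$data * 7.3
  a1 <- estimate_angular_offset(sino, sc$v, seq(-5, 5))
  a2 <- estimate_angular_offset(sino_scaled, sc$v, seq(-5, 5))
  expect_equal(a1$objective_curve$objective, a2$objective_curve$objective,
               tolerance = 1e-9)
})

test_that("a dead-time-dilated angular step is recovered within the grid", {
  sc <- slice_scenario()
  # 2% dead time: true step 1.02 deg while 1.00 deg is recorded
  dyn <- simulate_scan(sc$wet, dynamic_protocol(n_projections = 180, seed = 4,
                                                dead_time = 0.001,
                                                photons_per_pixel = 5000), sc$geom)
  sino <- retrieve_projections(dyn)
  als <- estimate_angular_step(sino, sc$v, seq(0.96, 1.08, by = 0.02))
  expect_equal(als$estimate, 1.02)
  # nominal data recover the nominal step
  dyn0 <- simulate_scan(sc$wet, dynamic_protocol(n_projections = 180, seed = 4,
                                photons_per_pixel = 5000),
                        sc$geom)
  als0 <- estimate_angular_step(retrieve_projections(dyn0), sc$v,
                                seq(0.96, 1.08, by = 0.02))
  expect_equal(als0$estimate, 1.00)
})

test_that("a mid-scan 16-frame skip appears as a 16-step offset change", {
  sc <- slice_scenario()
  dynk <- simulate_scan(sc$wet,
                        dynamic_protocol(n_projections = 360, seed = 5,
                                         photons_per_pixel = 5000,
                                         frame_skip = list(at = 180, n = 16)),
                        sc$geom)
  sk <- retrieve_projections(dynk)
  res <- split_on_discontinuity(sk, sc$v, boundaries = 181L, grid = seq(-4, 20))
  seg <- attr(res, "segments")
  expect_equal(seg$offset, c(0, 16))
  # without a skip both segments agree at zero
  dyn0 <- simulate_scan(sc$wet, dynamic_protocol(n_projections = 360, seed = 6,
                                         photons_per_pixel = 5000),
                        sc$geom)
  res0 <- split_on_discontinuity(retrieve_projections(dyn0), sc$v,
                                 boundaries = 181L, grid = seq(-5, 5))
  expect_equal(attr(res0, "segments")$offset, c(0, 0))
  # degenerate split: single segment equals the plain offset search
  res1 <- split_on_discontinuity(sk, sc$v, boundaries = integer(),
                                 grid = seq(-2, 2))
  plain <- estimate_angular_offset(sk, sc$v, seq(-2, 2))
  expect_equal(res1[[1]]$estimate, plain$estimate)
  expect_error(split_on_discontinuity(sk, sc$v, boundaries = 356L),
               "shorter than the minimum")
})

test_that("flat objectives are reported as non-informative", {
  sino <- sinogram(matrix(0, 30, 32), seq(0, 174, by = 6))
  v <- volume_image(matrix(0, 32, 32))
  expect_error(estimate_angular_offset(sino, v, seq(-3, 3)), "non-informative|flat")
})
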