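geom0 <- system_geometry(sigma_s = 0, sigma_d = 0)   # blur-free for closed forms

test_that("contact image reduces to Beer-Lambert closed forms", {
  n <- 64
  vx <- effective_pixel_size(geom0)
  empty <- array(0, c(n, n, 1))
  ci <- contact_image(empty, empty, 17, geom0)
  expect_equal(ci$attenuation, matrix(1, n, 1))
  expect_equal(ci$phase, matrix(0, n, 1))
  # uniform slab: attenuation exp(-mu T) across the slab's detector shadow
  beta <- 2e-10
  slab <- array(0, c(n, n, 1)); slab[, 21:40, 1] <- beta
  ci <- contact_image(array(0, dim(slab)), slab, 0, geom0)
  mu <- 4 * pi * beta / geom0$lambda
  expect_equal(unname(ci$attenuation[10, 1]), exp(-mu * 20 * vx), tolerance = 1e-10)
  expect_error(contact_image(slab, -slab, 0, geom0), "negative beta")
})

test_that("disc line integrals match the analytic chord length", {
  n <- 256
  vx <- effective_pixel_size(geom0)
  beta <- 1e-10
  disc <- array(aa_disc(n, 80, beta), c(n, n, 1))
  mu <- 4 * pi * beta / geom0$lambda
  chord <- disc_chord(n, 80) * mu * vx
  for (ang in c(0, 33.5, 90, 121)) {
    ci <- contact_image(array(0, dim(disc)), disc, ang, geom0)
    got <- -log(ci$attenuation[, 1])
    expect_lt(sqrt(mean((got - chord)^2)) / max(chord), 0.01)
  }
})

test_that("TIE intensity has the correct limits and quadratic-phase response", {
  n <- 64
  att <- matrix(0.7, n, 1)
  phase <- matrix(rnorm(n), n, 1)
  gc <- system_geometry(R2 = 0, sigma_s = 0, sigma_d = 0)
  expect_equal(tie_intensity(att, phase, gc), att / magnification(gc)^2)
  flat_phase <- matrix(3.2, n, 1)
  expect_equal(tie_intensity(att, flat_phase, geom0),
               att / magnification(geom0)^2)
  # quadratic phase: Laplacian = 4a exactly (interior)
  a <- 1e-6
  vx <- effective_pixel_size(geom0)
  g <- (seq_len(n) - (n + 1) / 2) * vx
  phi <- outer(g^2, g^2, "+") * a
  I <- tie_intensity(matrix(1, n, n), phi, geom0)
  M <- magnification(geom0)
  cte <- geom0$r2 * geom0$lambda / (2 * pi * M)
  expect_equal(unname(I[10:50, 10:50]),
               matrix((1 - cte * 4 * a) / M^2, 41, 41), tolerance = 1e-10)
})

test_that("system blur is flux-conserving and reproduces a sampled Gaussian", {
  g <- system_geometry()     # sigma = 29.8 um, 2.86 effective pixels
  img <- matrix(runif(64 * 8), 64, 8)
  out <- apply_system_blur(img, g)
  expect_equal(sum(out), sum(img), tolerance = 1e-9)
  expect_identical(apply_system_blur(img, g, sigma_um = 0), img)
  # centred point input -> sampled Gaussian
  pt <- matrix(0, 129, 129); pt[65, 65] <- 1
  s_pix <- system_psf_width(g$magnification, g$sigma_s, g$sigma_d) / g$pixel_eff
  out <- apply_system_blur(pt, g)
  x <- seq_len(129) - 65
  k2 <- exp(-outer(x^2, x^2, "+") / (2 * s_pix^2))
  k2 <- k2 / sum(k2)
  expect_lt(max(abs(out - k2)), 1e-6)
})

test_that("dynamic scan bookkeeping spans 9 s and 180 degrees", {
  p <- dynamic_protocol(n_projections = 180, exposure = 0.05,
                        angular_velocity = 20)
  tm <- dtvtomo:::protocol_timing(p)
  duration <- p$n_projections * p$exposure
  expect_equal(duration, 9)
  expect_equal(p$angular_velocity * duration, 180)
  step <- diff(tm$nominal_angles)[1]
  expect_equal(diff(range(tm$nominal_angles)) + step, 180)
  expect_equal(diff(range(tm$nominal_times)) + p$exposure, 9)
})

test_that("simulated scans are seed-deterministic", {
  ph <- build_phantom(3, c(48, 48), seed = 2)
  pr <- scan_protocol("static", n_projections = 24, angular_range = 180,
                      exposure = 0.1, photons_per_pixel = 500, seed = 8)
  s1 <- simulate_scan(ph, pr, geom0)
  s2 <- simulate_scan(ph, pr, geom0)
  expect_identical(s1$intensity, s2$intensity)
  expect_identical(s1$flat, s2$flat)
})

test_that("noise vanishes in the high-flux limit", {
  ph <- build_phantom(3, c(48, 48), seed = 2)
  mk <- function(photons) scan_protocol("static", n_projections = 20,
                                        angular_range = 180, exposure = 0.1,
                                        photons_per_pixel = photons, seed = 3)
  noiseless <- corrected_ratio(simulate_scan(ph, mk(Inf), geom0))
  noisy <- corrected_ratio(simulate_scan(ph, mk(1e8), geom0))
  expect_lt(sqrt(mean((noisy - noiseless)^2)) / mean(noiseless), 1e-3)
})

test_that("edge fringe contrast grows with propagation distance up to the optimum", {
  # slab edge, fixed system length R1 + R2 = 460 mm; optimum at R2 = 140
  n <- 96
  vx <- 10                                  # fixed object/detector grid pitch
  ph <- build_phantom(0, c(n, n), voxel_size = vx)
  maps <- optics_maps(ph)
  fringe <- vapply(c(20, 60, 100, 140), function(R2) {
    g <- system_geometry(R1 = 460 - R2, R2 = R2)
    ci <- contact_image(maps$delta, maps$beta, 0, g, voxel_size = vx)
    I <- tie_intensity(ci$attenuation, ci$phase, g, pixel_size = vx)
    I <- apply_system_blur(I, g, pixel_size = vx) * magnification(g)^2
    base <- apply_system_blur(ci$attenuation, g, pixel_size = vx)
    max(I - base) / mean(base)              # phase overshoot above attenuation
  }, numeric(1))
  expect_true(all(diff(fringe) > 0))
})

test_that("with delta = 0 the simulator is a plain attenuation CT", {
  n <- 96
  optics <- list(air = c(delta = 0, beta = 0),
                 wood = c(delta = 0, beta = 4e-10),
                 water = c(delta = 0, beta = 5.1e-10))
  ph <- build_phantom(2, c(n, n), seed = 4, material_optics = optics)
  pr <- scan_protocol("static", n_projections = 180, angular_range = 180,
                      exposure = 1, photons_per_pixel = Inf, seed = 1)
  ps <- simulate_scan(ph, pr, geom0)
  rec <- fbp_reconstruct(attenuation_sinogram(ps), filter = "ramlak")
  mu_truth <- 4 * pi * optics_maps(ph)$beta / geom0$lambda
  core <- dtvtomo:::grad_near_boundary
  wood <- ph$labels == 1L & !core(ph$labels == 1L)
  expect_equal(mean(rec$values[wood]), mean(mu_truth[wood]), tolerance = 0.02)
  expect_lt(sd(rec$values[wood]) / mean(mu_truth[wood]), 0.05)
})

test_that("timeline shorter than the scan signals an error", {
  ph <- build_phantom(1, c(32, 32), seed = 1)
  timeline <- function(t) if (t > 0.5) NULL else ph
  pr <- scan_protocol("continuous", n_projections = 40, exposure = 0.05,
                      angular_velocity = 20, photons_per_pixel = Inf)
  expect_error(simulate_scan(timeline, pr, geom0), "shorter than")
})
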