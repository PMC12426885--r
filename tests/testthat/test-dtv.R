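test_that("normalised gradient has the right limits", {
  expect_true(all(normalized_gradient(matrix(5, 16, 16), eta = 0.1)$x == 0))
  # linear ramp with slope far above eta points along x with near-unit norm
  ramp <- matrix(rep(seq_len(32), 32), 32, 32) * 10
  xi <- normalized_gradient(ramp, eta = 1e-3)
  expect_equal(unname(xi$x[5, 5, 1]), 10 / sqrt(100 + 1e-6), tolerance = 1e-10)
  expect_equal(unname(xi$y[5, 5, 1]), 0)
  # hard edge: |xi| -> 1 as gradient/eta -> infinity, but always < 1
  step <- matrix(c(rep(0, 8), rep(1e3, 8)), 16, 16)
  m <- dtvtomo:::grad_magnitude(normalized_gradient(step, eta = 1e-3))
  expect_true(all(m < 1))
  expect_gt(max(m), 1 - 1e-10)
})

test_that("the directional weight removes the prior-parallel component", {
  # xi = 0: identity
  xi0 <- normalized_gradient(matrix(0, 8, 8), eta = 1)
  g <- dtvtomo:::grad_forward(matrix(withr::with_seed(4, rnorm(64)), 8, 8))
  w <- apply_prior_weight(xi0, g)
  expect_equal(w$x, g$x); expect_equal(w$y, g$y)
  # g parallel to a unit xi is annihilated
  xi <- xi0; xi$x[] <- 1; xi$y[] <- 0
  gpar <- list(x = xi$x * 3.3, y = xi$y)
  expect_true(all(abs(apply_prior_weight(xi, gpar)$x) < 1e-12))
  # 3-voxel worked example against the explicit 2x2 matrix product
  xs <- c(0.6, -0.3, 0); ys <- c(0.5, 0.8, 0.9)
  gx <- c(1, -2, 0.5); gy <- c(0.25, 4, -1)
  xi3 <- list(x = array(xs, c(3, 1, 1)), y = array(ys, c(3, 1, 1)))
  class(xi3) <- "prior_xi"
  g3 <- list(x = array(gx, c(3, 1, 1)), y = array(gy, c(3, 1, 1)))
  w3 <- apply_prior_weight(xi3, g3)
  for (i in 1:3) {
    D <- diag(2) - c(xs[i], ys[i]) %*% t(c(xs[i], ys[i]))
    expected <- D %*% c(gx[i], gy[i])
    expect_equal(c(w3$x[i, 1, 1], w3$y[i, 1, 1]), as.numeric(expected))
  }
  expect_error(apply_prior_weight(xi3, g), "shape mismatch")
})

test_that("dTV functional: flat prior gives TV; aligned prior suppresses it", {
  u <- matrix(withr::with_seed(8, rnorm(400)), 20, 20)
  flat_prior <- prior_field(matrix(0, 20, 20), eta = 1)
  g <- dtvtomo:::grad_forward(u)
  tv <- sum(sqrt(g$x^2 + g$y^2))
  expect_equal(dtv_functional(u, flat_prior), tv)
  expect_equal(dtv_functional(matrix(2, 20, 20), flat_prior), 0)
  # piecewise-constant v, u = v, eta -> 0: gradient-parallel suppression
  v <- matrix(0, 32, 32); v[10:22, 8:25] <- 1
  pr <- prior_field(v, eta = 1e-8)
  expect_lt(dtv_functional(v, pr) / sum(dtvtomo:::grad_magnitude(
    dtvtomo:::grad_forward(v))), 1e-2)
})

test_that("objective_value matches its compositional recomputation", {
  n <- 24
  u <- matrix(withr::with_seed(3, runif(n * n)), n, n)
  ang <- seq(0, 160, by = 20)
  b <- forward_project(volume_image(u, voxel_size = 2), ang)
  b$data <- b$data + 0.1
  pr <- prior_field(matrix(0, n, n), eta = 1)
  alpha <- 0.37
  direct <- objective_value(volume_image(u, voxel_size = 2), b, pr, alpha)
  res <- forward_project(volume_image(u, voxel_size = 2), ang)$data - b$data
  expect_equal(direct, 0.5 * sum(res^2) + alpha * dtv_functional(u, pr),
               tolerance = 1e-12)
  expect_equal(objective_value(volume_image(u * 0, voxel_size = 2),
                               sinogram(b$data * 0, ang, pixel_size = 2),
                               pr, 1), 0)
})

test_that("unregularised PDHG converges to the least-squares solution", {
  n <- 32
  disc <- aa_disc(n, 10, value = 2)
  ang <- seq(0, 177, by = 3)
  sino <- forward_project(volume_image(disc, voxel_size = 1), ang)
  cfg <- recon_config(alpha = 0, n_iterations = 300, init = "fbp",
                      filter = "ramlak")
  rec <- pdhg_reconstruct(sino, prior_field(disc, eta = 1e-3), cfg)
  res <- forward_project(rec, ang)$data - sino$data
  expect_lt(sqrt(sum(res^2)) / sqrt(sum(sino$data^2)), 1e-3)
  expect_true(all(rec$values >= 0))
})

test_that("zero iterations return the clipped FBP warm start", {
  n <- 32
  obj <- matrix(withr::with_seed(2, rnorm(n * n)), n, n)  # signed values
  ang <- seq(0, 170, by = 10)
  sino <- forward_project(volume_image(obj, voxel_size = 1), ang)
  cfg <- recon_config(alpha = 1, n_iterations = 0)
  rec <- pdhg_reconstruct(sino, prior_field(obj, eta = 1e-3), cfg)
  fbp <- fbp_reconstruct(sino)
  expect_equal(rec$values, pmax(fbp$values, 0), tolerance = 1e-12)
})

test_that("the objective decreases in the net over PDHG iterations", {
  sc <- slice_scenario()
  dyn <- simulate_scan(sc$wet, dynamic_protocol(n_projections = 90, seed = 3),
                       sc$geom)
  sino <- retrieve_projections(dyn)
  rec <- pdhg_reconstruct(sino, prior_field(sc$v), recon_config(n_iterations = 12))
  obj <- attr(rec, "convergence")$objective
  expect_lt(obj[length(obj)], obj[1])
  for (k in seq_len(length(obj) - 3)) {
    expect_lt(obj[k + 3], obj[k] * 1.05)
  }
  expect_true(all(rec$values >= 0))
})

test_that("prior-aligned edges stay put while value changes are allowed", {
  # a vessel fills (air -> water) but keeps its shape: the fitted edge
  # centre of the regularised reconstruction matches the prior's within one
  # voxel, both above the front (static air-wood wall) and below it
  # (water-wood wall, where the interface material changed)
  rs <- res_scenario()
  centre_of <- function(vol, z) {
    f <- erf_fwhm(extract_edge_profile(vol, along = "x", at = rs$iy, slice = z,
                                       range = seq(rs$ix, min(rs$ix + 22, rs$n))))
    attr(f, "centre")
  }
  for (z in c(29, 4)) {    # above / below the waterfront
    shift <- centre_of(rs$dtv, z) - centre_of(rs$v, z)
    expect_lt(abs(shift), rs$vx)
  }
})
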