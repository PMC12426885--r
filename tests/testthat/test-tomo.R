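angles90 <- seq(0, 178, by = 2)

test_that("forward projection is linear and matches the disc chord", {
  n <- 256
  disc <- aa_disc(n, 80)
  sino <- forward_project(volume_image(disc, voxel_size = 1), angles90)
  chord <- disc_chord(n, 80)
  for (k in seq(1, 90, by = 13)) {
    expect_lt(sqrt(mean((sino$data[k, , 1] - chord)^2)) / max(chord), 0.01)
  }
  expect_true(all(forward_project(volume_image(disc * 0, voxel_size = 1),
                                  angles90)$data == 0))
  u1 <- matrix(withr::with_seed(1, rnorm(n * n)), n, n)
  u2 <- matrix(withr::with_seed(2, rnorm(n * n)), n, n)
  p <- get("forward_project")
  s12 <- p(volume_image(u1 + u2, voxel_size = 1), angles90)$data
  expect_equal(s12, p(volume_image(u1, voxel_size = 1), angles90)$data +
                 p(volume_image(u2, voxel_size = 1), angles90)$data,
               tolerance = 1e-12)
  expect_error(forward_project(volume_image(disc, voxel_size = 1), numeric()),
               "empty angle")
})

test_that("back projection is the exact adjoint on several geometries", {
  for (cfg in list(list(n = 32, ang = seq(0, 170, by = 10), h = 1),
                   list(n = 48, ang = seq(0, 350, by = 14.5), h = 10.43),
                   list(n = 27, ang = c(3, 45.2, 88, 133), h = 2))) {
    pr <- build_projector(cfg$n, cfg$ang, pixel_size = cfg$h)
    u <- withr::with_seed(5, rnorm(cfg$n^2))
    y <- withr::with_seed(6, rnorm(length(cfg$ang) * cfg$n))
    lhs <- sum(as.numeric(pr$A %*% u) * y)
    rhs <- sum(u * as.numeric(Matrix::crossprod(pr$A, y)))
    expect_lt(abs(lhs - rhs) / abs(rhs), 1e-6)
  }
})

test_that("back projection support and zero behaviour", {
  sino0 <- sinogram(matrix(0, 10, 32), seq(0, 171, by = 19))
  expect_true(all(back_project(sino0)$values == 0))
  one <- matrix(0, 10, 32); one[3, 16] <- 1
  bp <- back_project(sinogram(one, seq(0, 171, by = 19)))
  expect_gt(sum(bp$values != 0), 0)
  expect_lt(mean(bp$values != 0), 0.1)     # a single smeared ray
  # geometry mismatch is refused
  pr <- build_projector(16, c(0, 90))
  expect_error(back_project(sinogram(matrix(0, 10, 32), seq(0, 90, by = 10)),
                            projector = pr), "does not match")
})

test_that("FBP reconstructs a disc accurately away from the edge", {
  n <- 256
  disc <- aa_disc(n, 80)
  sino <- forward_project(volume_image(disc, voxel_size = 1), angles90)
  rec <- fbp_reconstruct(sino, filter = "ramlak")
  g <- seq_len(n) - (n + 1) / 2
  rr <- sqrt(outer(g^2, g^2, "+"))
  expect_lt(sqrt(mean((rec$values[, , 1][rr < 75] - 1)^2)), 0.02)
  # DC fidelity of the centred disc
  expect_equal(mean(rec$values[, , 1][rr < 120]) / mean(disc[rr < 120]), 1,
               tolerance = 0.05)
  # physical pixel scaling: same answer with 10 um voxels
  sino10 <- forward_project(volume_image(disc, voxel_size = 10), angles90)
  rec10 <- fbp_reconstruct(sino10, filter = "ramlak")
  expect_equal(rec10$values, rec$values, tolerance = 1e-6)
})

test_that("undersampled FBP is strictly worse and error shrinks ~1/angles", {
  # in the streak-dominated (severely undersampled) regime the error against
  # the converged angular sampling decays roughly inversely with angle count
  n <- 128
  g <- seq_len(n) - (n + 1) / 2
  blob <- exp(-((outer(g, rep(1, n)) - 45)^2 + (outer(rep(1, n), g) - 20)^2) /
                (2 * 2^2))
  vol <- volume_image(blob, voxel_size = 1)
  rec_of <- function(na) {
    ang <- seq(0, 180, length.out = na + 1)[1:na]
    fbp_reconstruct(forward_project(vol, ang), filter = "ramlak")$values[, , 1]
  }
  ref <- rec_of(1024)              # converged angular sampling
  err <- vapply(c(8, 16, 32, 360), function(na) sqrt(mean((rec_of(na) - ref)^2)),
                numeric(1))
  expect_gt(err[1], err[4])        # 8-angle streaks exceed well-sampled error
  ratio1 <- err[1] / err[2]
  ratio2 <- err[2] / err[3]
  expect_gt(ratio1, 1.4); expect_lt(ratio1, 2.6)
  expect_gt(ratio2, 1.4); expect_lt(ratio2, 2.6)
})

test_that("power-method norm matches closed forms and a dense SVD", {
  id <- function(x) x
  expect_equal(operator_norm(id, id, length_in = 50, seed = 2), 1,
               tolerance = 1e-6)
  sc <- function(x) 3 * x
  expect_equal(operator_norm(sc, sc, length_in = 50, seed = 2,
                             n_iterations = 5), 3, tolerance = 1e-9)
  m <- matrix(withr::with_seed(9, rnorm(64)), 8, 8)
  est <- operator_norm(function(x) as.numeric(m %*% x),
                       function(y) as.numeric(crossprod(m, y)),
                       length_in = 8, seed = 3, n_iterations = 200)
  expect_equal(est, max(svd(m)$d), tolerance = 0.01)
  # estimates are non-decreasing with iterations
  ests <- vapply(c(2, 5, 10, 40), function(k)
    operator_norm(function(x) as.numeric(m %*% x),
                  function(y) as.numeric(crossprod(m, y)),
                  length_in = 8, seed = 3, n_iterations = k), numeric(1))
  expect_true(all(diff(ests) >= -1e-12))
})
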