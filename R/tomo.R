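# Discrete parallel-beam tomography: Joseph-type forward projector assembled
# as a sparse matrix (its transpose is the exact adjoint used by the solver),
# filtered backprojection with the band-limited ramp kernel, and power-method
# operator norms.

#' Sinogram container
#'
#' @param data Matrix (`n_angles x n_det`) or 3D array (`n_angles x n_det x
#'   n_slices`) of line-integral projections.
#' @param angles Projection angles in degrees (one per row).
#' @param pixel_size Detector/reconstruction pixel size at the sample plane
#'   (micrometres).
#' @param timestamps Optional acquisition times in seconds.
#' @param kind Value semantics of the rays, e.g. `"mu_path"` (post-log
#'   attenuation) or `"delta_path"` (retrieved-phase refractive path).
#' @return A `sinogram` object.
#' @export
sinogram <- function(data, angles, pixel_size = 1, timestamps = NULL,
                     kind = "mu_path") {
  if (length(dim(data)) == 2L) data <- array(data, c(dim(data), 1L))
  stopifnot(length(angles) == dim(data)[1], all(is.finite(data)))
  if (is.null(timestamps)) timestamps <- rep(0, length(angles))
  structure(list(data = data, angles = as.numeric(angles),
                 timestamps = timestamps,
                 pixel_size = pixel_size, kind = kind),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sinogram> %d angles x %d bins x %d slices [%s] @ %.2f um\n",
              d[1], d[2], d[3], x$kind, x$pixel_size))
  invisible(x)
}

#' Volume image container
#'
#' @param values Matrix (`n x n`) or array (`n x n x nz`) of voxel values on
#'   an isotropic grid.
#' @param voxel_size Voxel size in micrometres.
#' @param semantics `"mu"` (linear attenuation, 1/um) or `"delta"`
#'   (refractive index decrement, dimensionless).
#' @return A `volume_image` object.
#' @export
volume_image <- function(values, voxel_size = 1, semantics = c("mu", "delta")) {
  semantics <- match.arg(semantics)
  if (length(dim(values)) == 2L) values <- array(values, c(dim(values), 1L))
  stopifnot(dim(values)[1] == dim(values)[2])
  structure(list(values = values, voxel_size = voxel_size, semantics = semantics),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_image> %d x %d x %d voxels @ %.2f um [%s], range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$voxel_size, x$semantics,
              min(x$values), max(x$values)))
  invisible(x)
}

# Extract the slice stack as a plain (n, n, nz) array.
vol_values <- function(v) if (inherits(v, "volume_image")) v$values else {
  if (length(dim(v)) == 2L) array(v, c(dim(v), 1L)) else v
}

#' Build a parallel-beam projection operator
#'
#' Assembles the Joseph-type (bilinearly interpolated ray-driven) discrete
#' Radon transform for a square `n x n` grid as a sparse matrix.  Rays are
#' parameterised by detector coordinate `s` on a detector of `n_det` bins
#' with the same pitch as the voxels; rotation is counter-clockwise about
#' the grid centre.  Row blocks are angle-major.  The transpose of the
#' returned matrix is the exact numerical adjoint used by iterative solvers.
#'
#' @param n Grid side length (voxels).
#' @param angles Projection angles in degrees.
#' @param n_det Number of detector bins (defaults to `n`).
#' @param pixel_size Voxel/detector pitch in micrometres; line integrals are
#'   scaled to physical units.
#' @return A `projector` object wrapping the sparse system matrix.
#' @export
build_projector <- function(n, angles, n_det = n, pixel_size = 1) {
  if (!length(angles)) stop("empty angle list")
  th <- angles * pi / 180
  cx <- (n + 1) / 2; cd <- (n_det + 1) / 2
  parts <- vector("list", length(th))
  sdet <- seq_len(n_det) - cd
  for (a in seq_along(th)) {
    c_ <- cos(th[a]); s_ <- sin(th[a])
    if (abs(s_) <= abs(c_)) {
      j <- seq_len(n)
      xi <- outer(sdet, (j - cx) * s_, "-") / c_ + cx
      i0 <- floor(xi); fr <- xi - i0
      scale <- 1 / abs(c_)
      J <- rep(j, each = n_det)
      d <- rep.int(seq_len(n_det), n)
      ii <- c(i0, i0 + 1); ww <- c(1 - fr, fr) * scale
      jj <- c(J, J); dd <- c(d, d)
      ok <- ii >= 1 & ii <= n & ww > 0
      parts[[a]] <- list(r = (a - 1L) * n_det + dd[ok],
                         q = (jj[ok] - 1L) * n + ii[ok], w = ww[ok])
    } else {
      i <- seq_len(n)
      yj <- outer(sdet, (i - cx) * c_, "-") / s_ + cx
      j0 <- floor(yj); fr <- yj - j0
      scale <- 1 / abs(s_)
      I <- rep(i, each = n_det)
      d <- rep.int(seq_len(n_det), n)
      jj <- c(j0, j0 + 1); ww <- c(1 - fr, fr) * scale
      ii <- c(I, I); dd <- c(d, d)
      ok <- jj >= 1 & jj <= n & ww > 0
      parts[[a]] <- list(r = (a - 1L) * n_det + dd[ok],
                         q = (jj[ok] - 1L) * n + ii[ok], w = ww[ok])
    }
  }
  A <- Matrix::sparseMatrix(
    i = unlist(lapply(parts, `[[`, "r"), use.names = FALSE),
    j = unlist(lapply(parts, `[[`, "q"), use.names = FALSE),
    x = unlist(lapply(parts, `[[`, "w"), use.names = FALSE) * pixel_size,
    dims = c(length(th) * n_det, n * n))
  structure(list(A = A, n = as.integer(n), n_det = as.integer(n_det),
                 angles = angles, pixel_size = pixel_size),
            class = "projector")
}

# Small cache so repeated calls with the same geometry reuse the sparse
# matrix (operator assembly dominates otherwise).
.projector_cache <- new.env(parent = emptyenv())

get_projector <- function(n, angles, n_det = n, pixel_size = 1) {
  key <- paste0(n, ":", n_det, ":", signif(pixel_size, 10), ":",
                paste(signif(angles, 10), collapse = ","))
  key <- substr(digest_key(key), 1, 32)
  hit <- .projector_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- build_projector(n, angles, n_det, pixel_size)
  keys <- ls(.projector_cache)
  if (length(keys) >= 4) rm(list = keys[1], envir = .projector_cache)
  assign(key, p, envir = .projector_cache)
  p
}

# Cheap stable key without external digest dependencies.
digest_key <- function(s) {
  v <- utf8ToInt(s)
  h1 <- 0; h2 <- 0
  for (x in v) { h1 <- (h1 * 31 + x) %% 2147483647; h2 <- (h2 * 131 + x) %% 2147483629 }
  paste0(h1, "x", h2, "x", nchar(s))
}

#' Forward project a volume
#'
#' Discrete parallel-beam line integrals of a volume at the given angles,
#' slice by slice, scaled to physical units by the voxel size.
#'
#' @param volume A [volume_image()], matrix or 3D array.
#' @param angles Projection angles in degrees (ignored when `projector` is
#'   given).
#' @param projector Optional pre-built [build_projector()] operator.
#' @param voxel_size Voxel size (micrometres) when `volume` is a bare array.
#' @return A [sinogram()] with `n_angles x n_det x nz` data.
#' @export
forward_project <- function(volume, angles = NULL, projector = NULL,
                            voxel_size = NULL) {
  u <- vol_values(volume)
  stopifnot(all(is.finite(u)))
  h <- voxel_size %||% (if (inherits(volume, "volume_image")) volume$voxel_size else 1)
  if (is.null(projector)) {
    if (is.null(angles) || !length(angles)) stop("empty angle list")
    projector <- get_projector(dim(u)[1], angles, pixel_size = h)
  }
  nz <- dim(u)[3]
  p <- projector$A %*% matrix(u, ncol = nz)
  out <- array(as.numeric(p), c(projector$n_det, length(projector$angles), nz))
  sinogram(aperm(out, c(2, 1, 3)), projector$angles, pixel_size = h,
           kind = if (inherits(volume, "volume_image") &&
                      volume$semantics == "delta") "delta_path" else "mu_path")
}

#' Backproject a sinogram (exact adjoint of the forward projector)
#'
#' Applies the transpose of the sparse forward operator.  This is the
#' adjoint required by first-order solvers, not a filtered backprojection;
#' see [fbp_reconstruct()] for the analytic inverse.
#'
#' @param sino A [sinogram()].
#' @param projector Optional pre-built operator (must match the sinogram
#'   geometry).
#' @return A [volume_image()].
#' @export
back_project <- function(sino, projector = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  d <- dim(sino$data)
  if (is.null(projector))
    projector <- get_projector(d[2], sino$angles, n_det = d[2],
                               pixel_size = sino$pixel_size)
  if (projector$n_det != d[2] || length(projector$angles) != d[1])
    stop("projector geometry does not match sinogram")
  y <- matrix(aperm(sino$data, c(2, 1, 3)), ncol = d[3])
  u <- Matrix::crossprod(projector$A, y)
  volume_image(array(as.numeric(u), c(projector$n, projector$n, d[3])),
               voxel_size = sino$pixel_size,
               semantics = if (sino$kind == "delta_path") "delta" else "mu")
}

# Band-limited ramp filter (spatial-domain construction, so the DC response
# is exact), with optional Hann apodisation.
ramp_filter_rows <- function(rows, h, filter = c("hann", "ramlak")) {
  filter <- match.arg(filter)
  n_det <- ncol(rows)
  N <- 2^ceiling(log2(2 * n_det))
  m <- c(0:(N / 2), (-N / 2 + 1):(-1))
  hk <- numeric(N)
  hk[m == 0] <- 1 / (4 * h^2)
  odd <- m %% 2 != 0
  hk[odd] <- -1 / (pi * m[odd] * h)^2
  H <- Re(stats::fft(hk))
  if (filter == "hann") {
    f <- fftfreq(N)
    H <- H * 0.5 * (1 + cos(pi * f / 0.5))
  }
  pad <- matrix(0, nrow(rows), N)
  pad[, seq_len(n_det)] <- rows
  ft <- t(stats::mvfft(t(pad)))
  q <- Re(t(stats::mvfft(t(ft * rep(H, each = nrow(rows))), inverse = TRUE))) / N
  q[, seq_len(n_det), drop = FALSE] * h
}

#' Filtered backprojection reconstruction
#'
#' Parallel-beam FBP (ramp-filtered, linearly interpolated pixel-driven
#' backprojection), applied independently to each slice of the sinogram.
#' Angular coverage beyond 180 degrees is weighted down for redundancy.
#'
#' @param sino A [sinogram()] (at least 2 angles).
#' @param filter `"hann"` (default) or `"ramlak"` apodisation of the ramp.
#' @param angles Optional replacement angles in degrees (used by the
#'   alignment search to test candidate offsets without copying data).
#' @return A [volume_image()].
#' @export
fbp_reconstruct <- function(sino, filter = c("hann", "ramlak"), angles = NULL) {
  filter <- match.arg(filter)
  stopifnot(inherits(sino, "sinogram"))
  d <- dim(sino$data)
  if (d[1] < 2) stop("need at least 2 angles")
  ang <- angles %||% sino$angles
  h <- sino$pixel_size
  th <- ang * pi / 180
  n <- d[2]
  cx <- (n + 1) / 2
  xs <- seq_len(n) - cx
  X <- matrix(xs, n, n); Y <- matrix(xs, n, n, byrow = TRUE)
  sp <- sort(th)
  dth <- median(diff(sp))
  coverage <- diff(range(th)) + dth
  fac <- if (coverage > 1.5 * pi) 0.5 else 1
  out <- array(0, c(n, n, d[3]))
  for (z in seq_len(d[3])) {
    q <- ramp_filter_rows(sino$data[, , z, drop = TRUE], h, filter)
    if (d[1] == 1L) q <- matrix(q, 1L)
    u <- matrix(0, n, n)
    for (k in seq_along(th)) {
      si <- (X * cos(th[k]) + Y * sin(th[k])) + cx
      i0 <- floor(si); fr <- si - i0
      v0 <- ifelse(i0 >= 1 & i0 <= n, q[k, pmin(pmax(i0, 1L), n)], 0)
      v1 <- ifelse(i0 + 1 >= 1 & i0 + 1 <= n, q[k, pmin(pmax(i0 + 1L, 1L), n)], 0)
      u <- u + (1 - fr) * v0 + fr * v1
    }
    out[, , z] <- u * dth * fac
  }
  volume_image(out, voxel_size = h,
               semantics = if (sino$kind == "delta_path") "delta" else "mu")
}

#' Power-method estimate of an operator norm
#'
#' Estimates the largest singular value of a linear operator given as an
#' apply/adjoint pair of closures, via power iteration on the normal
#' operator.  The Rayleigh-quotient estimate is non-decreasing over
#' iterations.
#'
#' @param apply Function mapping a primal vector (or list of arrays) to the
#'   operator's range.
#' @param adjoint The adjoint map.
#' @param x0 Start vector; drawn from a seeded standard normal when a length
#'   and seed are given instead.
#' @param n_iterations Number of power iterations (>= 1).
#' @param length_in Length of the primal space (used to draw `x0`).
#' @param seed Seed for the random start vector.
#' @return The norm estimate (scalar).
#' @export
operator_norm <- function(apply, adjoint, x0 = NULL, n_iterations = 20,
                          length_in = NULL, seed = 1L) {
  stopifnot(n_iterations >= 1)
  if (is.null(x0)) {
    stopifnot(!is.null(length_in))
    x0 <- with_seed(as.integer(seed), stats::rnorm(length_in))
  }
  x <- relist_like(unlist(x0) / sqrt(sum(unlist(x0)^2)), x0)
  L <- 0
  for (k in seq_len(n_iterations)) {
    y <- apply(x)
    L <- sqrt(sum(unlist(y)^2))     # ||K x|| with ||x|| = 1
    x <- adjoint(y)
    nx <- sqrt(sum(unlist(x)^2))
    if (nx == 0) return(0)
    x <- relist_like(unlist(x) / nx, x)
  }
  L
}

relist_like <- function(flat, template) {
  if (!is.list(template)) {
    out <- template
    out[] <- flat
    return(out)
  }
  out <- template
  pos <- 0L
  for (i in seq_along(out)) {
    n <- length(unlist(out[[i]]))
    out[[i]] <- relist_like(flat[pos + seq_len(n)], out[[i]])
    pos <- pos + n
  }
  out
}
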