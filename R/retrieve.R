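# Single-distance (Paganin-type) phase retrieval: Fourier-filter inversion of
# the near-field TIE under the homogeneous-object assumption with a known
# delta/beta ratio.

#' Spatial-frequency grid for a detector image
#'
#' Frequencies in cycles per micrometre on the effective-pixel grid, DC at
#' element (1, 1), matching the layout of the unshifted 2D DFT.
#'
#' @param shape Integer vector `c(nx, ny)` of the image shape.
#' @param pixel_size Pixel pitch in micrometres.
#' @return List with matrices `u` and `v` of the grid shape.
#' @export
frequency_grid <- function(shape, pixel_size) {
  fu <- fftfreq(shape[1], d = pixel_size)
  fv <- if (shape[2] > 1) fftfreq(shape[2], d = pixel_size) else 0
  list(u = matrix(fu, shape[1], shape[2]),
       v = matrix(fv, shape[1], shape[2], byrow = TRUE))
}

#' Low-pass retrieval filter
#'
#' The Fourier-domain denominator of the homogeneous TIE inversion:
#' `1 / ((lambda R2 / (4 pi M)) * (delta/beta) * k^2 + 1)` with `k` the
#' angular spatial frequency (`2 pi` times the cyclic frequencies of
#' [frequency_grid()]).  Equals 1 at DC and decays towards high frequency;
#' `R2 = 0` gives the identity filter.
#'
#' @param grid A [frequency_grid()].
#' @param geom A [system_geometry()].
#' @return Matrix of filter values in `(0, 1]`.
#' @export
retrieval_filter <- function(grid, geom) {
  k2 <- (2 * pi)^2 * (grid$u^2 + grid$v^2)   # rad^2 / um^2
  coef <- geom$lambda * geom$r2 / (4 * pi * geom$magnification) * geom$delta_beta
  1 / (coef * k2 + 1)
}

#' Retrieve the projected phase from one corrected projection
#'
#' Inverts the TIE for a homogeneous object:
#' `phi = -(1/2) (delta/beta) log |F^-1( F(I/I0) / filter... )|`, i.e. the
#' measured ratio is low-pass filtered in the Fourier domain and the
#' Beer-Lambert log then converts it to the (positive) projected phase
#' magnitude `(2 pi / lambda) * integral of delta`.  Images are mirror-padded
#' to twice their size before the transform to suppress wrap-around.
#'
#' @param projection Corrected intensity ratio `I/I0` (matrix `n_det x nz`).
#' @param geom A [system_geometry()].
#' @param pad Mirror-pad before the FFT (default TRUE).
#' @param clamp Floor applied to the filtered ratio before the log; the
#'   number of clamped pixels is reported via a warning.
#' @return Real phase image of the input shape.
#' @export
retrieve_phase <- function(projection, geom, pad = TRUE, clamp = 1e-6) {
  m <- as.matrix(projection)
  if (any(!is.finite(m))) stop("non-finite projection values")
  worig <- dim(m)
  if (pad) m <- mirror_pad(m)
  grid <- frequency_grid(dim(m), geom$pixel_eff)
  flt <- retrieval_filter(grid, geom)
  ft <- stats::fft(m) * flt
  rec <- Mod(stats::fft(ft, inverse = TRUE)) / length(m)
  rec <- rec[seq_len(worig[1]), seq_len(worig[2]), drop = FALSE]
  n_clamped <- sum(rec < clamp)
  if (n_clamped > 0)
    warning(sprintf("%d non-positive pixels clamped before log", n_clamped))
  rec <- pmax(rec, clamp)
  -0.5 * geom$delta_beta * log(rec)
}

mirror_pad <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  if (n1 > 1) m <- rbind(m, m[n1:1, , drop = FALSE])
  if (n2 > 1) m <- cbind(m, m[, n2:1, drop = FALSE])
  m
}

#' Phase retrieval of a whole projection set
#'
#' Applies flat/dark correction and [retrieve_phase()] to every projection
#' and converts the retrieved phase to refractive path length
#' `integral of delta = phi * lambda / (2 pi)`, producing the sinogram used
#' by the phase-retrieved reconstruction routes.
#'
#' @param pset A [simulate_scan()] result.
#' @param geom Optional geometry override (defaults to the set's own); use
#'   this to sweep `delta_beta` candidates.
#' @param delta_beta Optional `delta/beta` override.
#' @param pad,clamp Passed to [retrieve_phase()].
#' @return A [sinogram()] with kind `"delta_path"`.
#' @export
retrieve_projections <- function(pset, geom = NULL, delta_beta = NULL,
                                 pad = TRUE, clamp = 1e-6) {
  geom <- geom %||% pset$geom
  if (!is.null(delta_beta)) geom$delta_beta <- delta_beta
  r <- corrected_ratio(pset)
  d <- dim(r)
  out <- array(0, c(d[3], d[1], d[2]))
  n_clamped <- 0L
  for (i in seq_len(d[3])) {
    phi <- withCallingHandlers(
      retrieve_phase(r[, , i, drop = TRUE], geom, pad = pad, clamp = clamp),
      warning = function(w) { n_clamped <<- n_clamped + 1L; invokeRestart("muffleWarning") })
    out[i, , ] <- phi * geom$lambda / (2 * pi)
  }
  if (n_clamped > 0)
    warning(sprintf("clamped pixels in %d projections", n_clamped))
  sinogram(out, pset$angles, pixel_size = pset$voxel_size,
           timestamps = pset$timestamps, kind = "delta_path")
}

#' Sweep of delta/beta retrieval candidates
#'
#' Renders FBP reconstructions of one slice for a list of `delta/beta`
#' values, for the empirical tuning workflow used with polychromatic
#' sources: the user inspects fringe removal, noise and CNR across the sweep
#' and picks a value; no automatic criterion is applied.
#'
#' @param pset A [simulate_scan()] result.
#' @param delta_beta_values Numeric vector of candidate ratios.
#' @param slice Slice index to reconstruct.
#' @param filter FBP apodisation.
#' @return A tibble with `delta_beta` and the reconstructed slice (list
#'   column `volume`).
#' @export
delta_beta_sweep <- function(pset, delta_beta_values, slice = 1L,
                             filter = "hann") {
  rows <- lapply(delta_beta_values, function(db) {
    sino <- retrieve_projections(pset, delta_beta = db)
    sino$data <- sino$data[, , slice, drop = FALSE]
    v <- fbp_reconstruct(sino, filter = filter)
    tibble::tibble(delta_beta = db, volume = list(v))
  })
  do.call(rbind, rows)
}
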