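# Forward simulation of free-space-propagation phase-contrast projections:
# Beer-Lambert contact image, near-field TIE intensity, system blur, and
# Poisson counting noise, for static reference scans and continuous-rotation
# dynamic scans of a time-evolving phantom.

#' Scan protocol
#'
#' @param mode `"static"` (object frozen, angles equally spaced over
#'   `angular_range`) or `"continuous"` (object evolves while rotating at
#'   `angular_velocity`).
#' @param n_projections Number of projections (>= 1).
#' @param angular_range Total angular range in degrees (static mode).
#' @param exposure Exposure time per projection in seconds.
#' @param angular_velocity Rotation speed in degrees per second (continuous
#'   mode, > 0).
#' @param photons_per_pixel Expected flat-field counts per detector pixel per
#'   exposure; `Inf` disables counting noise.
#' @param seed Integer seed for the Poisson noise.
#' @param offset_deg True start-angle offset of the rotation stage relative
#'   to the nominal zero recorded with the data (used to exercise the
#'   alignment estimators).
#' @param dead_time Detector dead time per frame in seconds; the true angular
#'   step becomes `angular_velocity * (exposure + dead_time)` while the
#'   recorded nominal step assumes no dead time.
#' @param frame_skip Optional `list(at = index, n = frames)`: the detector
#'   silently drops `n` frames after projection `at`, so later projections
#'   are acquired at angles offset by `n` steps while the recorded angles
#'   remain nominal.
#' @param dark_level Expected dark counts per pixel.
#' @param n_flats Number of flat frames averaged into the stored flat field.
#' @param supersample Integer phantom supersampling factor for the line
#'   integrals (2 simulates on a finer grid than any reconstruction, avoiding
#'   the inverse crime); 1 reuses the reconstruction grid.
#' @return A `scan_protocol` object.
#' @export
scan_protocol <- function(mode = c("static", "continuous"),
                          n_projections = 180L,
                          angular_range = 180,
                          exposure = 0.05,
                          angular_velocity = 20,
                          photons_per_pixel = 1000,
                          seed = 1L,
                          offset_deg = 0,
                          dead_time = 0,
                          frame_skip = NULL,
                          dark_level = 10,
                          n_flats = 20L,
                          supersample = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_projections >= 1, exposure > 0,
            mode != "continuous" || angular_velocity > 0,
            supersample %in% c(1L, 2L))
  structure(as.list(environment()), class = "scan_protocol")
}

#' Reference (high-quality) scan protocol
#'
#' Static well-sampled scan emulating a long reference acquisition: many
#' projections over a full turn with a long exposure.  Defaults are scaled
#' for desk-size grids; the instrument configuration this emulates used 1001
#' projections of 1 s over 360 degrees.
#' @param n_projections,exposure,photons_per_pixel,seed,... Passed through to
#'   [scan_protocol()].
#' @return A `scan_protocol`.
#' @export
reference_protocol <- function(n_projections = 360L, exposure = 1,
                               photons_per_pixel = 20000, seed = 100L, ...) {
  scan_protocol(mode = "static", n_projections = n_projections,
                angular_range = 360, exposure = exposure,
                photons_per_pixel = photons_per_pixel, seed = seed, ...)
}

#' Dynamic (continuous-rotation) scan protocol
#'
#' Continuous flyscan at 20 degrees per second with 50 ms exposures: 180
#' projections span 9 s and 180 degrees, the temporal resolution of one
#' dynamic CT frame.
#' @param n_projections,exposure,angular_velocity,photons_per_pixel,seed,...
#'   Passed through to [scan_protocol()].
#' @return A `scan_protocol`.
#' @export
dynamic_protocol <- function(n_projections = 180L, exposure = 0.05,
                             angular_velocity = 20, photons_per_pixel = 1000,
                             seed = 1L, ...) {
  scan_protocol(mode = "continuous", n_projections = n_projections,
                exposure = exposure, angular_velocity = angular_velocity,
                photons_per_pixel = photons_per_pixel, seed = seed, ...)
}

# Nominal (recorded) and true (simulated) angle/time bookkeeping.
protocol_timing <- function(protocol) {
  i <- seq_len(protocol$n_projections) - 1L
  if (protocol$mode == "static") {
    ang <- protocol$offset_deg + i * protocol$angular_range / protocol$n_projections
    nominal <- i * protocol$angular_range / protocol$n_projections
    t_mid <- rep(0, length(i))
    t_nom <- i * protocol$exposure
  } else {
    frame <- i
    if (!is.null(protocol$frame_skip))
      frame <- ifelse(i >= protocol$frame_skip$at, i + protocol$frame_skip$n, i)
    period <- protocol$exposure + protocol$dead_time
    t_mid <- (frame + 0.5) * period
    ang <- protocol$offset_deg + protocol$angular_velocity * t_mid
    t_nom <- i * protocol$exposure
    nominal <- protocol$angular_velocity * (i + 0.5) * protocol$exposure
  }
  list(true_angles = ang, nominal_angles = nominal,
       true_times = t_mid, nominal_times = t_nom)
}

#' Contact image of a phantom at one angle
#'
#' Line integrals of the optical constants at a single projection angle:
#' the Beer-Lambert transmission `exp(-integral of mu)` with
#' `mu = 4 pi beta / lambda`, and the projected phase
#' `phi = -(2 pi / lambda) * integral of delta`.
#'
#' @param delta_map,beta_map Co-registered arrays (2D slice or 3D volume).
#' @param angle Projection angle in degrees.
#' @param geom A [system_geometry()].
#' @param voxel_size Voxel size of the maps in micrometres (defaults to the
#'   effective pixel size of `geom`).
#' @return List with `attenuation` and `phase` detector images
#'   (`n_det x nz` matrices).
#' @export
contact_image <- function(delta_map, beta_map, angle, geom,
                          voxel_size = effective_pixel_size(geom)) {
  if (any(beta_map < 0)) stop("negative beta rejected")
  stopifnot(identical(dim(delta_map), dim(beta_map)) ||
              identical(length(delta_map), length(beta_map)))
  d <- vol_values(delta_map); b <- vol_values(beta_map)
  mu <- 4 * pi * b / geom$lambda              # 1/um
  proj <- function(m) {
    p <- get_projector(dim(m)[1], angle, pixel_size = voxel_size)
    matrix(as.numeric(p$A %*% matrix(m, ncol = dim(m)[3])), nrow = p$n_det)
  }
  list(attenuation = exp(-proj(mu)),
       phase = -(2 * pi / geom$lambda) * proj(d))
}

#' Near-field TIE intensity at the detector
#'
#' Transport-of-intensity model of the propagated image:
#' `I = (contact / M^2) * (1 - (R2 lambda / (2 pi M)) * laplacian(phi))`,
#' with the transverse Laplacian evaluated by a 5-point stencil with
#' reflective boundaries on the effective-pixel grid.  Negative intensities
#' (weak-object violations) are clipped to zero with a warning.
#'
#' @param attenuation_image,phase_image Detector images from
#'   [contact_image()].
#' @param geom A [system_geometry()].
#' @param pixel_size Grid pitch of the detector images in micrometres
#'   (defaults to the geometry's effective pixel size).
#' @return Detector intensity image (relative to unit incident intensity at
#'   the object plane).
#' @export
tie_intensity <- function(attenuation_image, phase_image, geom,
                          pixel_size = geom$pixel_eff) {
  M <- geom$magnification
  cte <- geom$r2 * geom$lambda / (2 * pi * M)    # um^2
  lap <- laplacian5(as.matrix(phase_image)) / pixel_size^2
  I <- (attenuation_image / M^2) * (1 - cte * lap)
  nneg <- sum(I < 0)
  if (nneg > 0) {
    warning(sprintf("TIE intensity clipped at 0 for %d pixels (weak-object violation)", nneg))
    I[I < 0] <- 0
  }
  I
}

# 5-point Laplacian, reflective boundary, unit grid spacing.
laplacian5 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  up <- m[c(1, seq_len(n1 - 1)), , drop = FALSE]
  dn <- m[c(seq_len(n1 - 1) + 1, n1), , drop = FALSE]
  out <- up + dn - 2 * m
  if (n2 > 1) {
    lf <- m[, c(1, seq_len(n2 - 1)), drop = FALSE]
    rt <- m[, c(seq_len(n2 - 1) + 1, n2), drop = FALSE]
    out <- out + lf + rt - 2 * m
  }
  out
}

#' Apply the total system PSF to a detector image
#'
#' Gaussian convolution with the system PSF width of the geometry, expressed
#' in effective pixels, with reflective boundaries; total flux is conserved.
#'
#' @param detector_image Matrix (`n_det x nz`).
#' @param geom A [system_geometry()].
#' @param sigma_um Optional override of the blur width in micrometres.
#' @param pixel_size Grid pitch of the detector image in micrometres
#'   (defaults to the geometry's effective pixel size).
#' @return Blurred image of the same shape.
#' @export
apply_system_blur <- function(detector_image, geom, sigma_um = NULL,
                              pixel_size = geom$pixel_eff) {
  s <- sigma_um %||% system_psf_width(geom$magnification, geom$sigma_s, geom$sigma_d)
  s_pix <- s / pixel_size
  if (s_pix <= 0) return(detector_image)
  gauss_blur(detector_image, s_pix)
}

#' Simulate a phase-contrast CT scan
#'
#' Runs the full forward chain per projection: contact image of the phantom
#' state at the exposure midpoint, TIE propagation, system blur, and Poisson
#' counting noise with dark and flat frames.
#'
#' @param phantom_timeline Either a static [build_phantom()] object or a
#'   function `t -> vessel_phantom` describing the evolving sample.
#' @param protocol A [scan_protocol()].
#' @param geom A [system_geometry()].
#' @return A `projection_set`: intensity array (`n_det x nz x
#'   n_projections`), flat and dark images, recorded (nominal) angles and
#'   timestamps, plus the true angles used by the simulation.
#' @export
simulate_scan <- function(phantom_timeline, protocol, geom) {
  timeline <- if (is.function(phantom_timeline)) phantom_timeline
              else function(t) phantom_timeline
  tm <- protocol_timing(protocol)
  ph0 <- timeline(tm$true_times[1])
  if (is.null(ph0)) stop("phantom timeline undefined at scan start")
  d <- ph0$grid_shape
  ss <- protocol$supersample
  n_det <- d[1] %/% 1L
  nz <- d[3]
  intensity <- array(0, c(n_det, nz, protocol$n_projections))
  warn_clip <- 0L
  for (i in seq_len(protocol$n_projections)) {
    ph <- timeline(tm$true_times[i])
    if (is.null(ph)) stop("phantom timeline shorter than scan duration")
    maps <- optics_maps(ph)
    if (ss > 1L) {
      maps$delta <- upsample2(maps$delta, ss)
      maps$beta <- upsample2(maps$beta, ss)
    }
    vx <- ph$voxel_size / ss
    ci <- contact_image(maps$delta, maps$beta, tm$true_angles[i], geom,
                        voxel_size = vx)
    if (ss > 1L) {   # rebin detector rows to the nominal pitch
      ci$attenuation <- rebin_rows(ci$attenuation, ss)
      ci$phase <- rebin_rows(ci$phase, ss)
    }
    I <- withCallingHandlers(
      tie_intensity(ci$attenuation, ci$phase, geom),
      warning = function(w) {
        warn_clip <<- warn_clip + 1L
        invokeRestart("muffleWarning")
      })
    I <- apply_system_blur(I, geom)
    intensity[, , i] <- I
  }
  if (warn_clip > 0)
    warning(sprintf("TIE intensity clipped in %d projections", warn_clip))
  M2 <- geom$magnification^2
  flat_expected <- matrix(protocol$photons_per_pixel, n_det, nz)
  dark_expected <- matrix(protocol$dark_level, n_det, nz)
  counts_expected <- intensity * M2 * protocol$photons_per_pixel
  if (is.finite(protocol$photons_per_pixel)) {
    with_seed(as.integer(protocol$seed), {
      intensity <- array(stats::rpois(length(counts_expected),
                                      counts_expected + protocol$dark_level),
                         dim(counts_expected))
      flat <- matrix(stats::rpois(length(flat_expected) * protocol$n_flats,
                                  rep(flat_expected + protocol$dark_level,
                                      protocol$n_flats)),
                     ncol = protocol$n_flats)
      flat <- matrix(rowMeans(flat), n_det, nz)
      dark <- matrix(stats::rpois(length(dark_expected) * protocol$n_flats,
                                  rep(dark_expected, protocol$n_flats)),
                     ncol = protocol$n_flats)
      dark <- matrix(rowMeans(dark), n_det, nz)
    })
  } else {
    # noiseless limit: unit flat field, no dark signal
    intensity <- intensity * M2
    flat <- matrix(1, n_det, nz)
    dark <- matrix(0, n_det, nz)
  }
  structure(list(intensity = intensity, flat = flat, dark = dark,
                 angles = tm$nominal_angles, timestamps = tm$nominal_times,
                 true_angles = tm$true_angles, true_times = tm$true_times,
                 protocol = protocol, geom = geom,
                 voxel_size = ph0$voxel_size, clipped = warn_clip),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<projection_set> %d projections of %d x %d pixels, %.4g-%.4g deg, %.3g s span\n",
              d[3], d[1], d[2], min(x$angles), max(x$angles),
              max(x$timestamps) + x$protocol$exposure))
  invisible(x)
}

#' Flat/dark-corrected intensity ratio of a projection set
#'
#' `(I - dark) / (flat - dark)`, the normalised transmission images the
#' retrieval and log-attenuation steps operate on.  With the geometry's
#' magnification the incident-beam scaling cancels in the ratio.
#'
#' @param pset A [simulate_scan()] result.
#' @return Array `n_det x nz x n_projections`.
#' @export
corrected_ratio <- function(pset) {
  den <- pset$flat - pset$dark
  sweep(sweep(pset$intensity, c(1, 2), pset$dark, "-"), c(1, 2), den, "/")
}

#' Log-attenuation sinogram from a projection set
#'
#' `-log` of the corrected ratio, i.e. line integrals of the linear
#' attenuation coefficient (1/um with micrometre pixels), as used by the
#' conventional reconstruction route.
#'
#' @param pset A [simulate_scan()] result.
#' @param clamp Floor applied to the ratio before the log.
#' @return A [sinogram()] with kind `"mu_path"`.
#' @export
attenuation_sinogram <- function(pset, clamp = 1e-6) {
  r <- pmax(corrected_ratio(pset), clamp)
  d <- dim(r)
  sinogram(aperm(array(-log(r), d), c(3, 1, 2)), pset$angles,
           pixel_size = pset$voxel_size, timestamps = pset$timestamps,
           kind = "mu_path")
}

upsample2 <- function(a, f) {
  d <- dim(a)
  out <- array(0, c(d[1] * f, d[2] * f, d[3]))
  for (z in seq_len(d[3]))
    out[, , z] <- a[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), z]
  out
}

rebin_rows <- function(m, f) {
  n <- nrow(m) / f
  out <- matrix(0, n, ncol(m))
  for (k in seq_len(f)) out <- out + m[seq(k, by = f, length.out = n), , drop = FALSE]
  out / f
}
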