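# Quantitative image metrics: contrast-to-noise ratio, Pearson correlation
# of normalised gradient directions, edge-response resolution, and region
# histograms.

#' Contrast-to-noise ratio between two grey-value samples
#'
#' `CNR = (mean_a - mean_b) / ((sd_a + sd_b) / 2)`: the class separation in
#' units of the mean within-class standard deviation.  The sign follows the
#' argument order.
#'
#' @param values_a,values_b Numeric samples (>= 2 values each).
#' @return Scalar CNR.
#' @seealso [cnr_from_stats()] for published mean/sd summaries.
#' @export
cnr <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  cnr_from_stats(mean(values_a), sd(values_a), mean(values_b), sd(values_b))
}

#' Contrast-to-noise ratio from summary statistics
#'
#' @param mean_a,sd_a,mean_b,sd_b Class means and standard deviations.
#' @return `(mean_a - mean_b) / ((sd_a + sd_b) / 2)`.
#' @export
cnr_from_stats <- function(mean_a, sd_a, mean_b, sd_b) {
  pooled <- (sd_a + sd_b) / 2
  if (any(pooled == 0)) stop("degenerate input: zero pooled standard deviation")
  (mean_a - mean_b) / pooled
}

#' Pearson correlation of normalised gradient directions
#'
#' Computes the eta-normalised gradient fields of two co-registered images
#' and correlates their concatenated vector components over the pixels where
#' both gradient magnitudes exceed a support threshold.  For two states of
#' the same structure set whose interiors change value but whose boundaries
#' stay fixed (with unchanged contrast sign), this correlation is 1 even
#' when the raw images have visibly decorrelated.
#'
#' @param image_a,image_b Matrices of identical shape.
#' @param eta Edge parameter of the gradient normalisation; also the default
#'   support threshold.
#' @param support Gradient-magnitude threshold defining the joint support.
#' @return Correlation in `[-1, 1]`.
#' @export
gradient_direction_correlation <- function(image_a, image_b, eta = 1e-3,
                                           support = eta) {
  stopifnot(identical(dim(image_a), dim(image_b)))
  ga <- grad_forward(as.matrix(image_a))
  gb <- grad_forward(as.matrix(image_b))
  ma <- grad_magnitude(ga); mb <- grad_magnitude(gb)
  keep <- ma > support & mb > support
  if (!any(keep)) stop("empty joint gradient support")
  na <- sqrt(ma^2 + eta^2); nb <- sqrt(mb^2 + eta^2)
  va <- c(ga$x[keep] / na[keep], ga$y[keep] / na[keep])
  vb <- c(gb$x[keep] / nb[keep], gb$y[keep] / nb[keep])
  pearson(va, vb)
}

#' Edge profile container
#'
#' @param positions Strictly increasing sample positions (micrometres).
#' @param values Grey values along the profile (>= 8 samples).
#' @return An `edge_profile`.
#' @export
edge_profile <- function(positions, values) {
  stopifnot(length(positions) == length(values), length(values) >= 8,
            all(diff(positions) > 0))
  structure(list(positions = positions, values = values), class = "edge_profile")
}

#' Extract an axis-aligned edge profile from a volume slice
#'
#' @param volume A [volume_image()] or matrix.
#' @param along `"x"` or `"y"`: profile axis within the slice.
#' @param at Index on the other in-plane axis.
#' @param slice Slice index (3D volumes).
#' @param range Optional index range along the profile axis.
#' @return An [edge_profile()] with positions in micrometres.
#' @export
extract_edge_profile <- function(volume, along = c("x", "y"), at, slice = 1L,
                                 range = NULL) {
  along <- match.arg(along)
  vv <- vol_values(volume)
  h <- if (inherits(volume, "volume_image")) volume$voxel_size else 1
  line <- if (along == "x") vv[, at, slice] else vv[at, , slice]
  idx <- range %||% seq_along(line)
  edge_profile(idx * h, line[idx])
}

#' Extract a through-slice (z) edge profile
#'
#' @param volume A [volume_image()] or 3D array.
#' @param x,y In-plane voxel indices of the profile line.
#' @param range Optional slice index range.
#' @return An [edge_profile()].
#' @export
extract_z_profile <- function(volume, x, y, range = NULL) {
  vv <- vol_values(volume)
  h <- if (inherits(volume, "volume_image")) volume$voxel_size else 1
  line <- vv[x, y, ]
  idx <- range %||% seq_along(line)
  edge_profile(idx * h, line[idx])
}

#' Gaussian-equivalent FWHM of an edge response function
#'
#' Least-squares fit of a scaled and shifted Gaussian-integral model
#' `low + (high - low) * Phi((x - x0) / sigma)` to the profile; the spatial
#' resolution is reported as `FWHM = 2 sqrt(2 ln 2) sigma ~ 2.3548 sigma`.
#' The profile must span both plateaus: the first and last 20% of samples
#' must sit within 20% of the fitted levels (of the edge height).
#'
#' @param profile An [edge_profile()].
#' @return The FWHM in the units of the profile positions, with the fit
#'   attached as attributes (`sigma`, `centre`, `levels`, `rmse`).
#' @export
erf_fwhm <- function(profile) {
  stopifnot(inherits(profile, "edge_profile"))
  x <- profile$positions; yv <- profile$values
  lo0 <- mean(head(yv, max(2, round(length(yv) * 0.2))))
  hi0 <- mean(tail(yv, max(2, round(length(yv) * 0.2))))
  x00 <- x[which.min(abs(yv - (lo0 + hi0) / 2))]
  s0 <- max(diff(range(x)) / 10, mean(diff(x)))
  fit <- NULL
  for (s_try in unique(c(s0, s0 / 4, s0 * 4, mean(diff(x)) / 4))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(yv ~ lo + (hi - lo) * pnorm((x - x0) / sg),
                        start = list(lo = lo0, hi = hi0, x0 = x00, sg = s_try),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # quantile-crossing fallback for degenerate (e.g. single-sample step)
    # edges where the least-squares Gaussian-integral fit is singular
    h25 <- lo0 + 0.25 * (hi0 - lo0); h75 <- lo0 + 0.75 * (hi0 - lo0)
    crossing <- function(level) {
      s <- sign(yv - level)
      i <- which(s != s[1])[1]
      if (is.na(i) || i == 1)
        stop(sprintf("edge fit did not converge (residual sd %.3g)", sd(yv)))
      x[i - 1] + (level - yv[i - 1]) / (yv[i] - yv[i - 1]) * (x[i] - x[i - 1])
    }
    sg_emp <- abs(crossing(h75) - crossing(h25)) / (2 * stats::qnorm(0.75))
    p <- c(lo = lo0, hi = hi0, x0 = (crossing(h25) + crossing(h75)) / 2,
           sg = max(sg_emp, .Machine$double.eps))
    res_sd <- NA_real_
  } else {
    p <- coef(fit)
    res_sd <- sqrt(mean(stats::resid(fit)^2))
  }
  height <- abs(p[["hi"]] - p[["lo"]])
  if (height == 0) stop("degenerate edge: zero height")
  n20 <- max(2, round(length(yv) * 0.2))
  if (mean(abs(head(yv, n20) - p[["lo"]])) > 0.2 * height ||
      mean(abs(tail(yv, n20) - p[["hi"]])) > 0.2 * height)
    stop("profile does not span both plateaus")
  sg <- abs(p[["sg"]])
  # resolution floor: a step sampled at pitch dx cannot measure below ~dx
  fwhm <- max(2 * sqrt(2 * log(2)) * sg, min(diff(x)) * 1e-9)
  attr(fwhm, "sigma") <- sg
  attr(fwhm, "centre") <- p[["x0"]]
  attr(fwhm, "levels") <- c(low = p[["lo"]], high = p[["hi"]])
  attr(fwhm, "rmse") <- res_sd
  fwhm
}

#' Region specification for material categories
#'
#' @param ... Named logical masks (or index vectors) over the volume grid,
#'   e.g. `air = `, `wood = `, `water = `.  Masks must be pairwise disjoint
#'   and non-empty.
#' @return A `region_spec`.
#' @export
region_spec <- function(...) {
  regions <- list(...)
  stopifnot(length(regions) > 0, !is.null(names(regions)),
            all(nzchar(names(regions))))
  idx <- lapply(regions, function(r) if (is.logical(r)) which(r) else as.integer(r))
  if (any(lengths(idx) == 0)) stop("empty region")
  all_idx <- unlist(idx)
  if (anyDuplicated(all_idx)) stop("regions must be disjoint")
  structure(idx, class = "region_spec")
}

#' Grey-value histograms and summaries per material category
#'
#' @param volume A [volume_image()] or array.
#' @param regions A [region_spec()].
#' @param bins Number of histogram bins over the pooled 1-99 percentile
#'   range.
#' @return A list with `histogram` (tibble: category, mid, count) and
#'   `summary` (tibble: category, n, mean, sd).
#' @export
material_histograms <- function(volume, regions, bins = 64) {
  vv <- as.numeric(vol_values(volume))
  if (max(unlist(regions)) > length(vv)) stop("region outside volume bounds")
  pooled <- unlist(lapply(regions, function(i) vv[i]))
  rng <- stats::quantile(pooled, c(0.01, 0.99), names = FALSE)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  rows <- lapply(names(regions), function(nm) {
    x <- vv[regions[[nm]]]
    xx <- pmin(pmax(x, rng[1]), rng[2])
    ct <- hist(xx, breaks = breaks, plot = FALSE)
    tibble::tibble(category = nm, mid = ct$mids, count = ct$counts)
  })
  summaries <- lapply(names(regions), function(nm) {
    x <- vv[regions[[nm]]]
    tibble::tibble(category = nm, n = length(x), mean = mean(x),
                   sd = if (length(x) > 1) sd(x) else 0)
  })
  list(histogram = do.call(rbind, rows), summary = do.call(rbind, summaries))
}

#' @importFrom graphics hist
NULL
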