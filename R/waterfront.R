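# Per-vessel water classification and waterfront tracking: voxels are
# classified as water by the grey-value difference to the dry reference,
# collapsed to a water-to-vessel thickness ratio R(z), and the front height
# extracted with a persistence rule that is robust to stray droplets and
# air inclusions.

#' Segment vessels from the high-quality reference volume
#'
#' Vessels are the air-filled tubes inside the wood cylinder of the dry
#' reference: voxels below an Otsu-initialised threshold, restricted to the
#' interior of the sample, grouped into near-axial tubes by labelling the
#' connected components of the column-wise air fraction.
#'
#' @param v Reference [volume_image()].
#' @param threshold Grey-value threshold separating air from wood (defaults
#'   to Otsu's threshold over the interior).
#' @param interior_frac Radius fraction of the grid treated as sample
#'   interior.
#' @param min_voxels Minimum in-plane component size (pixels) kept as a
#'   vessel.
#' @return Integer array of vessel labels (0 outside vessels) with the
#'   threshold stored as an attribute.
#' @export
segment_vessels <- function(v, threshold = NULL, interior_frac = 0.8,
                            min_voxels = 4L) {
  vv <- vol_values(v)
  d <- dim(vv)
  g <- seq_len(d[1]) - (d[1] + 1) / 2
  rr <- sqrt(outer(g^2, (seq_len(d[2]) - (d[2] + 1) / 2)^2, "+"))
  interior <- rr <= interior_frac * (min(d[1:2]) / 2 - 1)
  if (is.null(threshold)) {
    x <- vv[array(interior, d)]
    threshold <- EBImage::otsu(array((x - min(x)) / diff(range(x)), c(length(x), 1)),
                               range = c(0, 1)) * diff(range(x)) + min(x)
  }
  air <- (vv < threshold) & array(interior, d)
  frac <- apply(air, c(1, 2), mean)
  cols <- frac > 0.5
  lab2d <- EBImage::bwlabel(cols * 1)
  sizes <- tabulate(lab2d[lab2d > 0])
  keep <- which(sizes >= min_voxels)
  relab <- integer(max(lab2d, 1)); relab[keep] <- seq_along(keep)
  lab2d[lab2d > 0] <- relab[lab2d[lab2d > 0]]
  labels <- array(rep(as.integer(lab2d), d[3]), d)
  labels[!air] <- 0L
  attr(labels, "threshold") <- threshold
  labels
}

#' Classify water voxels from a dynamic/reference volume pair
#'
#' A vessel voxel contains water when its grey value exceeds the dry
#' reference by more than the classification threshold (the halfway point
#' between the water and air class means in the usual workflow; see
#' [halfway_threshold()]).
#'
#' @param u_t Dynamic [volume_image()] at time t.
#' @param v Co-registered dry reference.
#' @param vessel_mask Logical array (or label array, nonzero = vessel).
#' @param threshold Positive grey-value difference threshold.
#' @return Logical array: water voxels.
#' @export
classify_water <- function(u_t, v, vessel_mask, threshold) {
  stopifnot(threshold > 0)
  uu <- vol_values(u_t); vv <- vol_values(v)
  stopifnot(identical(dim(uu), dim(vv)))
  (vessel_mask != 0) & (uu - vv > threshold)
}

#' Halfway classification threshold from class means
#'
#' @param mean_water,mean_air Class mean grey values.
#' @return `(mean_water - mean_air) / 2`.
#' @export
halfway_threshold <- function(mean_water, mean_air) (mean_water - mean_air) / 2

#' Water-to-vessel projected thickness ratio
#'
#' Counts water and vessel voxels along one in-plane projection axis
#' (the coronal-plane thickness) and returns their ratio per height and
#' remaining in-plane position; `NA` where the vessel has no thickness.
#'
#' @param water_mask,vessel_mask Logical arrays of identical shape.
#' @param axis In-plane projection axis, 1 or 2.
#' @return Matrix `R` (remaining in-plane position x height), values in
#'   `[0, 1]` or `NA`.
#' @export
thickness_ratio <- function(water_mask, vessel_mask, axis = 1L) {
  stopifnot(identical(dim(water_mask), dim(vessel_mask)), axis %in% 1:2)
  wsum <- apply(water_mask & (vessel_mask != 0), c(3 - axis, 3), sum)
  vsum <- apply(vessel_mask != 0, c(3 - axis, 3), sum)
  out <- wsum / vsum
  out[vsum == 0] <- NA_real_
  out
}

# R(z) profile of one labelled vessel: total water / total vessel voxels per
# height.
vessel_ratio_profile <- function(water_mask, vessel_labels, id) {
  sel <- vessel_labels == id
  vsum <- apply(sel, 3, sum)
  wsum <- apply(water_mask & sel, 3, sum)
  r <- wsum / vsum
  r[vsum == 0] <- NA_real_
  r
}

#' Waterfront height from a thickness-ratio profile
#'
#' Scans upward from the vessel base and returns the first height at which
#' `R` drops below `ratio_threshold` and stays below it for `persistence`
#' consecutive voxels (the profile is treated as zero above the vessel top).
#' The persistence rule suppresses single-voxel air inclusions below the
#' front and stray droplets above it.
#'
#' @param R_profile Numeric vector `R(z)` from the vessel base upward (`NA`
#'   allowed where the vessel is absent).
#' @param ratio_threshold Threshold on `R` (default 0.1).
#' @param persistence Required run length in voxels (default 20).
#' @param voxel_size Voxel size in micrometres (1 returns voxel units).
#' @return Height of the front above the base (micrometres); the vessel top
#'   if `R` never stays below the threshold.
#' @export
front_height <- function(R_profile, ratio_threshold = 0.1, persistence = 20L,
                         voxel_size = 1) {
  stopifnot(persistence >= 1)
  if (all(is.na(R_profile))) stop("R undefined everywhere")
  r <- R_profile
  r[is.na(r)] <- 0
  below <- c(r < ratio_threshold, rep(TRUE, persistence))
  run <- 0L
  n <- length(r)
  for (z in seq_len(n)) {
    if (all(below[z:(z + persistence - 1L)]))
      return((z - 1L) * voxel_size)
  }
  n * voxel_size
}

#' Waterfront uncertainty from a threshold sweep
#'
#' Evaluates [front_height()] at a lower and upper ratio threshold; because
#' the detected height is monotone non-increasing in the threshold the two
#' results bracket the nominal-threshold height.
#'
#' @param R_profile As in [front_height()].
#' @param thresholds Two thresholds in (0, 1), default `c(0.05, 0.15)`.
#' @param persistence,voxel_size As in [front_height()].
#' @return Named vector `c(low, high)` of ordered bounds (micrometres).
#' @export
front_uncertainty <- function(R_profile, thresholds = c(0.05, 0.15),
                              persistence = 20L, voxel_size = 1) {
  stopifnot(length(thresholds) == 2, all(thresholds > 0), all(thresholds < 1))
  h <- vapply(thresholds, function(th)
    front_height(R_profile, th, persistence, voxel_size), numeric(1))
  c(low = min(h), high = max(h))
}

#' Track the waterfront of every vessel over a timeline
#'
#' Classifies water against the reference at each time point, collapses each
#' labelled vessel to its `R(z)` profile, and extracts the front height with
#' error bounds from the threshold sweep.  Returns per-vessel tracks plus a
#' cohort summary (median and standard deviation of the front height across
#' vessels at each time point).
#'
#' @param timeline Named or unnamed list of dynamic [volume_image()]s; names
#'   (or the `times` argument) give acquisition times in seconds.
#' @param v Dry reference [volume_image()].
#' @param vessel_labels Label array from [segment_vessels()].
#' @param threshold Water classification threshold (grey-value difference).
#' @param times Numeric acquisition times (defaults to names of `timeline`).
#' @param ratio_threshold,persistence Front extraction parameters.
#' @param sweep Threshold sweep for the error bounds.
#' @return A `vessel_tracks` object: tibble of per-vessel tracks
#'   (`vessel`, `t`, `h`, `h_low`, `h_high`), cohort summary, and a
#'   monotonicity flag per vessel.
#' @export
track_vessels <- function(timeline, v, vessel_labels, threshold,
                          times = NULL, ratio_threshold = 0.1,
                          persistence = 20L, sweep = c(0.05, 0.15)) {
  if (is.null(times)) times <- as.numeric(names(timeline))
  stopifnot(length(times) == length(timeline), !any(is.na(times)))
  voxel <- if (inherits(v, "volume_image")) v$voxel_size else 1
  ids <- sort(setdiff(unique(as.integer(vessel_labels)), 0L))
  rows <- list()
  for (ti in seq_along(timeline)) {
    u <- timeline[[ti]]
    water <- classify_water(u, v, vessel_labels, threshold)
    for (id in ids) {
      r <- vessel_ratio_profile(water, vessel_labels, id)
      if (all(is.na(r))) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          vessel = id, t = times[ti], h = NA_real_, h_low = NA_real_,
          h_high = NA_real_)
        next
      }
      h <- front_height(r, ratio_threshold, persistence, voxel)
      b <- front_uncertainty(r, sweep, persistence, voxel)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        vessel = id, t = times[ti], h = h, h_low = b[["low"]], h_high = b[["high"]])
    }
  }
  tracks <- do.call(rbind, rows)
  lost <- tracks$vessel[is.na(tracks$h)]
  if (length(lost))
    message("vessels missing at some time points: ", paste(unique(lost), collapse = ", "))
  cohort <- do.call(rbind, lapply(split(tracks, tracks$t), function(d) {
    tibble::tibble(t = d$t[1], median_h = median(d$h, na.rm = TRUE),
                   sd_h = sd(d$h, na.rm = TRUE), n = sum(!is.na(d$h)))
  }))
  cohort <- cohort[order(cohort$t), ]
  mono <- vapply(split(tracks, tracks$vessel), function(d) {
    d <- d[order(d$t), ]
    ok <- diff(d$h) >= -(d$h_high - d$h_low)[-nrow(d)] - 1e-9
    all(ok, na.rm = TRUE)
  }, logical(1))
  structure(list(tracks = tracks, cohort = cohort,
                 monotone = tibble::tibble(vessel = as.integer(names(mono)),
                                           monotone = unname(mono)),
                 voxel_size = voxel, threshold = threshold,
                 ratio_threshold = ratio_threshold, persistence = persistence),
            class = "vessel_tracks")
}

#' @export
print.vessel_tracks <- function(x, ...) {
  cat(sprintf("<vessel_tracks> %d vessels x %d time points, %d monotone\n",
              length(unique(x$tracks$vessel)), length(unique(x$tracks$t)),
              sum(x$monotone$monotone)))
  invisible(x)
}

#' @export
tidy.vessel_tracks <- function(x, ...) x$tracks

#' @export
glance.vessel_tracks <- function(x, ...) {
  tibble::tibble(n_vessels = length(unique(x$tracks$vessel)),
                 n_times = length(unique(x$tracks$t)),
                 frac_monotone = mean(x$monotone$monotone),
                 final_median_h = tail(x$cohort$median_h, 1))
}

#' Fit a power-law exponent to a vessel's front trajectory
#'
#' Linear fit of `log h` against `log t` over points with a measurable
#' front, estimating the exponent `p` of `h ~ t^p` (0.5 for capillary
#' square-root rise).
#'
#' @param tracks A `vessel_tracks` object.
#' @param vessel Vessel id.
#' @param min_height Minimum height (micrometres) for a point to enter the
#'   fit (suppresses voxel-quantisation bias near the base).
#' @return Tibble with the vessel, exponent, its standard error and the
#'   number of points used.
#' @export
fit_front_exponent <- function(tracks, vessel, min_height = 0) {
  d <- tracks$tracks[tracks$tracks$vessel == vessel, ]
  d <- d[!is.na(d$h) & d$h > min_height & d$t > 0, ]
  if (nrow(d) < 3) stop("not enough points to fit an exponent")
  fit <- stats::lm(log(h) ~ log(t), data = d)
  tibble::tibble(vessel = vessel,
                 exponent = unname(coef(fit)[2]),
                 se = summary(fit)$coefficients[2, 2],
                 n = nrow(d))
}

#' Detect a sharp jump in a front trajectory
#'
#' Finds the largest single-interval increase of `h(t)`; a joined vessel
#' pair separating produces a jump much larger than the capillary-rise
#' steps around it.
#'
#' @param tracks A `vessel_tracks` object.
#' @param vessel Vessel id.
#' @return Tibble with the jump time interval, the height before and after,
#'   and the jump size (micrometres).
#' @export
detect_front_jump <- function(tracks, vessel) {
  d <- tracks$tracks[tracks$tracks$vessel == vessel, ]
  d <- d[order(d$t), ]
  dh <- diff(d$h)
  i <- which.max(dh)
  tibble::tibble(vessel = vessel, t_before = d$t[i], t_after = d$t[i + 1],
                 h_before = d$h[i], h_after = d$h[i + 1], jump = dh[i])
}
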