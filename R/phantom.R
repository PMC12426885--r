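# Synthetic wood phantom: an in-air wood cylinder pierced by axial vessels
# that progressively fill with water.  Acts as the ground-truth generator for
# the whole pipeline (no public dataset of this kind exists).

MATERIAL_LEVELS <- c(air = 0L, wood = 1L, water = 2L)

default_material_optics <- function() {
  # (delta, beta) at the effective wavelength.  delta/beta = 1000 for the
  # condensed materials; air is treated as vacuum.  Values give the field's
  # typical ordering air < wood < water in delta at ~19 keV.
  list(air   = c(delta = 0,       beta = 0),
       wood  = c(delta = 4.0e-7,  beta = 4.0e-10),
       water = c(delta = 5.1e-7,  beta = 5.1e-10))
}

#' Build a wood-cylinder phantom with axial vessels
#'
#' Constructs a voxel phantom of a wood cylinder surrounded by air and pierced
#' by non-overlapping axial (z-aligned) cylindrical vessels, initially dry
#' (air-filled).  Optionally a number of vessel *pairs* are placed joined by a
#' thin wood membrane up to a separation height, emulating branching vessel
#' structure.
#'
#' @param n_vessels Number of single vessels (>= 0).
#' @param grid_shape Integer vector `c(nx, ny)` for a single axial slice or
#'   `c(nx, ny, nz)` for a volume.
#' @param voxel_size Isotropic voxel size in micrometres.
#' @param seed Integer seed; the phantom is deterministic given the seed.
#' @param radius_range Vessel radius range in micrometres.
#' @param n_paired Number of joined vessel pairs to add (each contributes two
#'   vessels sharing a membrane below `separation_z`).
#' @param cylinder_frac Wood cylinder radius as a fraction of the largest
#'   radius that fits the grid.
#' @param wood_texture Relative standard deviation of optional multiplicative
#'   fibrous texture applied to the wood optical constants (models the
#'   heterogeneous wood matrix and its sub-resolution porosity); 0 disables
#'   it.
#' @param texture_scale In-plane correlation length of the texture (voxels).
#' @param material_optics Named list of `c(delta, beta)` per material.
#'
#' @return A `vessel_phantom` object: integer label array (`0` air, `1` wood,
#'   `2` water), `vessel_table` tibble (id, x, y, radius, paired_with,
#'   separation_z), voxel size and material optics.
#' @export
build_phantom <- function(n_vessels, grid_shape = c(128L, 128L),
                          voxel_size = 15 / ((320 + 140) / 320),
                          seed = 1L,
                          radius_range = c(25, 60),
                          n_paired = 0L,
                          cylinder_frac = 0.85,
                          wood_texture = 0,
                          texture_scale = 2.5,
                          material_optics = default_material_optics()) {
  stopifnot(n_vessels >= 0, length(grid_shape) %in% c(2L, 3L),
            all(grid_shape >= 8L), voxel_size > 0, n_paired >= 0)
  nx <- as.integer(grid_shape[1]); ny <- as.integer(grid_shape[2])
  nz <- if (length(grid_shape) == 3L) as.integer(grid_shape[3]) else 1L
  r_cyl <- cylinder_frac * (min(nx, ny) / 2 - 1)        # voxels
  gx <- seq_len(nx) - (nx + 1) / 2
  gy <- seq_len(ny) - (ny + 1) / 2
  rr <- sqrt(outer(gx^2, gy^2, "+"))
  slice <- matrix(MATERIAL_LEVELS[["air"]], nx, ny)
  slice[rr <= r_cyl] <- MATERIAL_LEVELS[["wood"]]

  r_rng_vox <- sort(radius_range) / voxel_size
  placed <- NULL   # rows: x, y, radius (voxels)
  place_one <- function(radius_vox, near = NULL, gap_vox = 0) {
    for (attempt in seq_len(2000)) {
      if (is.null(near)) {
        cx <- stats::runif(1, -r_cyl, r_cyl); cy <- stats::runif(1, -r_cyl, r_cyl)
      } else {
        th <- stats::runif(1, 0, 2 * pi)
        d <- near$radius + radius_vox + gap_vox
        cx <- near$x + d * cos(th); cy <- near$y + d * sin(th)
      }
      if (sqrt(cx^2 + cy^2) + radius_vox + 2 > r_cyl) next
      if (!is.null(placed)) {
        dd <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)
        min_gap <- if (is.null(near)) 2 else 0.5
        if (any(dd < placed[, 3] + radius_vox + min_gap)) next
      }
      return(c(cx, cy, radius_vox))
    }
    NULL
  }

  tab <- list()
  id <- 0L
  with_seed(as.integer(seed), {
    for (v in seq_len(n_vessels)) {
      r <- stats::runif(1, r_rng_vox[1], r_rng_vox[2])
      p <- place_one(r)
      if (is.null(p))
        stop(sprintf("infeasible vessel packing: placed %d of %d vessels", v - 1L, n_vessels))
      placed <- rbind(placed, p)
      id <- id + 1L
      tab[[id]] <- tibble::tibble(id = id, x = p[1], y = p[2], radius = p[3] * voxel_size,
                                  paired_with = NA_integer_, separation_z = NA_real_)
    }
    for (v in seq_len(n_paired)) {
      r <- stats::runif(1, r_rng_vox[1], r_rng_vox[2])
      p1 <- place_one(r)
      if (is.null(p1))
        stop(sprintf("infeasible vessel packing: placed %d pairs of %d", v - 1L, n_paired))
      placed <- rbind(placed, p1)
      p2 <- place_one(r * 0.8, near = list(x = p1[1], y = p1[2], radius = p1[3]),
                      gap_vox = 1.2)
      if (is.null(p2))
        stop(sprintf("infeasible vessel packing: placed %d pairs of %d", v - 1L, n_paired))
      placed <- rbind(placed, p2)
      sep_z <- stats::runif(1, 0.4, 0.7) * nz * voxel_size
      i1 <- id + 1L; i2 <- id + 2L
      tab[[i1]] <- tibble::tibble(id = i1, x = p1[1], y = p1[2], radius = p1[3] * voxel_size,
                                  paired_with = i2, separation_z = sep_z)
      tab[[i2]] <- tibble::tibble(id = i2, x = p2[1], y = p2[2], radius = p2[3] * voxel_size,
                                  paired_with = i1, separation_z = sep_z)
      id <- id + 2L
    }
  })
  vessel_table <- if (id > 0) do.call(rbind, tab) else
    tibble::tibble(id = integer(), x = numeric(), y = numeric(), radius = numeric(),
                   paired_with = integer(), separation_z = numeric())

  # rasterise vessels into the slice (air inside wood)
  vmask2d <- array(0L, c(nx, ny))
  if (id > 0) {
    X <- matrix(gx, nx, ny); Y <- matrix(gy, nx, ny, byrow = TRUE)
    for (k in seq_len(nrow(vessel_table))) {
      rv <- vessel_table$radius[k] / voxel_size
      inside <- (X - vessel_table$x[k])^2 + (Y - vessel_table$y[k])^2 <= rv^2
      vmask2d[inside] <- vessel_table$id[k]
      slice[inside] <- MATERIAL_LEVELS[["air"]]
    }
  }

  labels <- array(rep(slice, nz), c(nx, ny, nz))
  vmask <- array(rep(vmask2d, nz), c(nx, ny, nz))
  texture <- NULL
  if (wood_texture > 0) {
    # fibrous in-plane texture with a correlation length of a few voxels
    # (constant along z, like axial wood fibres), scaled to the requested
    # relative standard deviation
    tex2d <- with_seed(as.integer(seed) + 7919L,
                       matrix(stats::rnorm(nx * ny), nx, ny))
    tex2d <- gauss_blur(tex2d, texture_scale)
    tex2d <- tex2d / stats::sd(tex2d) * wood_texture
    texture <- array(rep(exp(tex2d), nz), c(nx, ny, nz))
  }
  structure(list(labels = labels, vessel_map = vmask,
                 vessel_table = vessel_table,
                 voxel_size = voxel_size, grid_shape = c(nx, ny, nz),
                 cylinder_radius = r_cyl * voxel_size,
                 material_optics = material_optics,
                 wood_texture = wood_texture, texture = texture,
                 seed = as.integer(seed)),
            class = "vessel_phantom")
}

#' @export
print.vessel_phantom <- function(x, ...) {
  d <- x$grid_shape
  cat(sprintf("<vessel_phantom> %d x %d x %d voxels @ %.2f um, %d vessels, %.1f%% water\n",
              d[1], d[2], d[3], x$voxel_size, nrow(x$vessel_table),
              100 * mean(x$labels == MATERIAL_LEVELS[["water"]])))
  invisible(x)
}

#' Capillary filling schedule for a phantom's vessels
#'
#' Encodes a Lucas-Washburn-type rise law per vessel,
#' `h_i(t) = k_i * sqrt(max(0, t - t0_i))`, with the rate constant inversely
#' proportional to the vessel radius (narrower capillaries rise faster), plus
#' optional jump events `(time, height_jump, new_rate)` that emulate a joined
#' vessel pair separating: the front jumps by `height_jump` and continues with
#' the (typically larger) single-vessel rate.
#'
#' @param vessel_table The `vessel_table` of a [build_phantom()] result.
#' @param t0 Start time(s) in seconds (recycled across vessels).
#' @param k Explicit rate constants in um / sqrt(s) (optional; overrides
#'   `k_coef`).
#' @param k_coef Coefficient of the `k_i = k_coef / radius_i` law
#'   (um^2 / sqrt(s)).
#' @param events Optional tibble/data frame with columns `id`, `time`,
#'   `height_jump` (um) and `new_rate` (um / sqrt(s), `NA` keeps the old rate).
#' @return A `fill_schedule` tibble with one row per vessel.
#' @export
fill_schedule <- function(vessel_table, t0 = 0, k = NULL, k_coef = 2400,
                          events = NULL) {
  stopifnot(all(t0 >= 0))
  n <- nrow(vessel_table)
  sch <- tibble::tibble(
    id = vessel_table$id,
    t0 = rep_len(t0, n),
    k = if (!is.null(k)) rep_len(k, n) else k_coef / vessel_table$radius,
    jump_time = NA_real_, jump_height = 0, jump_rate = NA_real_
  )
  if (!is.null(events)) {
    for (r in seq_len(nrow(events))) {
      i <- match(events$id[r], sch$id)
      if (is.na(i)) stop("event refers to unknown vessel id ", events$id[r])
      sch$jump_time[i] <- events$time[r]
      sch$jump_height[i] <- events$height_jump[r] %||% 0
      sch$jump_rate[i] <- events$new_rate[r]
    }
  }
  class(sch) <- c("fill_schedule", class(sch))
  sch
}

# Front height (um above the vessel base) for every vessel at time t.
schedule_heights <- function(schedule, t) {
  h <- schedule$k * sqrt(pmax(0, t - schedule$t0))
  ev <- !is.na(schedule$jump_time) & t >= schedule$jump_time
  if (any(ev)) {
    h_pre <- schedule$k[ev] * sqrt(pmax(0, schedule$jump_time[ev] - schedule$t0[ev]))
    k_post <- ifelse(is.na(schedule$jump_rate[ev]), schedule$k[ev], schedule$jump_rate[ev])
    h[ev] <- h_pre + schedule$jump_height[ev] +
      k_post * sqrt(pmax(0, t - schedule$jump_time[ev]))
  }
  h
}

#' Water state of a phantom at a given time
#'
#' Relabels vessel voxels below each vessel's front height as water.  For a
#' single-slice (2D) phantom a vessel is water-filled once its front height is
#' positive.  Filling is monotone: the water set at `t1` is contained in the
#' water set at `t2 >= t1`; all non-vessel voxels are untouched.
#'
#' @param phantom A [build_phantom()] result (dry or previously filled).
#' @param schedule A [fill_schedule()].
#' @param t Time in seconds, `t >= 0`.
#' @return A new `vessel_phantom` with updated labels.
#' @export
fill_state <- function(phantom, schedule, t) {
  stopifnot(inherits(phantom, "vessel_phantom"), t >= 0)
  h <- schedule_heights(schedule, t)
  labels <- phantom$labels
  d <- phantom$grid_shape
  z_um <- (seq_len(d[3]) - 1) * phantom$voxel_size   # height of voxel base
  for (k in seq_along(schedule$id)) {
    vid <- schedule$id[k]
    if (h[k] <= 0) next
    zfill <- if (d[3] == 1L) 1L else which(z_um < h[k])
    if (!length(zfill)) next
    sel <- phantom$vessel_map[, , zfill, drop = FALSE] == vid
    sub <- labels[, , zfill, drop = FALSE]
    sub[sel] <- MATERIAL_LEVELS[["water"]]
    labels[, , zfill] <- sub
  }
  out <- phantom
  out$labels <- labels
  out
}

#' Voxelwise optical-constant maps of a phantom
#'
#' @param phantom A [build_phantom()] result.
#' @return List with `delta` and `beta` arrays of the phantom's grid shape.
#'   Wood voxels are modulated by the phantom's texture field if enabled.
#' @export
optics_maps <- function(phantom) {
  labs <- phantom$labels
  opt <- phantom$material_optics
  present <- sort(unique(as.integer(labs)))
  names_present <- names(MATERIAL_LEVELS)[match(present, MATERIAL_LEVELS)]
  missing <- names_present[!names_present %in% names(opt)]
  if (length(missing)) stop("missing material optics for: ", paste(missing, collapse = ", "))
  delta <- array(0, dim(labs)); beta <- array(0, dim(labs))
  for (m in names_present) {
    sel <- labs == MATERIAL_LEVELS[[m]]
    delta[sel] <- opt[[m]][["delta"]]
    beta[sel] <- opt[[m]][["beta"]]
  }
  if (!is.null(phantom$texture)) {
    wood <- labs == MATERIAL_LEVELS[["wood"]]
    delta[wood] <- delta[wood] * phantom$texture[wood]
    beta[wood] <- beta[wood] * phantom$texture[wood]
  }
  list(delta = delta, beta = beta)
}

#' Shape-preserving dynamic image pair
#'
#' Generates two 2D images of the same structure set in which a random subset
#' of vessel interiors changes grey value between the two states (the filling
#' of structures with a fluid), while every structure boundary stays in place
#' and keeps its contrast sign.  This is the situation in which the raw
#' images decorrelate but their normalised gradient directions stay perfectly
#' correlated, which is the basis for regularising dynamic reconstructions
#' with a static structural prior.
#'
#' @param seed Integer seed.
#' @param n Image side length in pixels.
#' @param n_vessels Number of vessel structures.
#' @return List with matrices `a` and `b`.
#' @export
figure1_pair <- function(seed = 1L, n = 128L, n_vessels = 8L) {
  ph <- build_phantom(n_vessels, grid_shape = c(n, n), seed = seed)
  lv <- c(air = 0, wood = 1, vessel_dry = 0.25, vessel_wet = 0.65)
  base <- matrix(lv[["air"]], n, n)
  base[ph$labels[, , 1] == MATERIAL_LEVELS[["wood"]]] <- lv[["wood"]]
  a <- base
  a[ph$vessel_map[, , 1] > 0] <- lv[["vessel_dry"]]
  b <- a
  ids <- ph$vessel_table$id
  wet <- with_seed(as.integer(seed) + 101L,
                   sample(ids, size = max(1L, floor(length(ids) / 2))))
  b[ph$vessel_map[, , 1] %in% wet] <- lv[["vessel_wet"]]
  list(a = a, b = b)
}

#' Material masks of a phantom
#'
#' Logical masks for the air-filled vessel voxels, wood, water and the
#' full vessel set, as used by the region-based metrics.
#'
#' @param phantom A [build_phantom()] or [fill_state()] result.
#' @return Named list of logical arrays.
#' @export
phantom_masks <- function(phantom) {
  list(air = phantom$labels == MATERIAL_LEVELS[["air"]] & phantom$vessel_map > 0,
       wood = phantom$labels == MATERIAL_LEVELS[["wood"]],
       water = phantom$labels == MATERIAL_LEVELS[["water"]],
       vessel = phantom$vessel_map > 0)
}
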