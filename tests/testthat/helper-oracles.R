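# Independent oracles and fixture builders used across the suite.

# Brute-force 3D connected-component count (6-connectivity) by frontier
# dilation; independent of any labelling used in the package.
count_components_3d <- function(mask) {
  d <- dim(mask)
  remaining <- which(mask)
  idx2xyz <- function(i) {
    i0 <- i - 1L
    cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
  }
  xyz2idx <- function(m) 1L + m[, 1] + d[1] * (m[, 2] + d[2] * m[, 3])
  n_comp <- 0L
  in_mask <- logical(prod(d)); in_mask[remaining] <- TRUE
  visited <- logical(prod(d))
  while (length(remaining)) {
    n_comp <- n_comp + 1L
    frontier <- remaining[1]
    visited[frontier] <- TRUE
    while (length(frontier)) {
      m <- idx2xyz(frontier)
      nb <- rbind(cbind(m[, 1] + 1L, m[, 2], m[, 3]),
                  cbind(m[, 1] - 1L, m[, 2], m[, 3]),
                  cbind(m[, 1], m[, 2] + 1L, m[, 3]),
                  cbind(m[, 1], m[, 2] - 1L, m[, 3]),
                  cbind(m[, 1], m[, 2], m[, 3] + 1L),
                  cbind(m[, 1], m[, 2], m[, 3] - 1L))
      ok <- nb[, 1] >= 0 & nb[, 1] < d[1] & nb[, 2] >= 0 & nb[, 2] < d[2] &
        nb[, 3] >= 0 & nb[, 3] < d[3]
      cand <- unique(xyz2idx(nb[ok, , drop = FALSE]))
      frontier <- cand[in_mask[cand] & !visited[cand]]
      visited[frontier] <- TRUE
    }
    remaining <- remaining[!visited[remaining]]
  }
  n_comp
}

# Anti-aliased disc on an n x n grid (pixel units), coverage-approximated.
aa_disc <- function(n, radius, value = 1) {
  g <- seq_len(n) - (n + 1) / 2
  rr <- sqrt(outer(g^2, g^2, "+"))
  value * pmin(pmax(radius + 0.5 - rr, 0), 1)
}

# Analytic parallel-beam chord length of a centred disc.
disc_chord <- function(n_det, radius) {
  s <- seq_len(n_det) - (n_det + 1) / 2
  ifelse(abs(s) <= radius, 2 * sqrt(pmax(radius^2 - s^2, 0)), 0)
}

# Brute-force waterfront rule: first z such that R < thr over a persistence
# window (profile zero-padded above the top).
front_height_bruteforce <- function(r, thr, persistence) {
  r[is.na(r)] <- 0
  rr <- c(r, rep(0, persistence))
  for (z in seq_along(r)) {
    if (all(rr[z:(z + persistence - 1)] < thr)) return(z - 1L)
  }
  length(r)
}

# Noisy delta-map volume of a phantom state (volume-domain emulation of a
# well-converged reconstruction with a given class-gap-relative noise).
noisy_delta_volume <- function(phantom, noise_sd, seed, voxel = phantom$voxel_size) {
  d <- optics_maps(phantom)$delta
  vals <- d + array(withr::with_seed(seed, stats::rnorm(length(d), 0, noise_sd)),
                    dim(d))
  volume_image(vals, voxel_size = voxel, semantics = "delta")
}

# Shared small textured slice phantom scenarios (cached per session so
# several tests can reuse the same simulated scans).
.scenario_cache <- new.env(parent = emptyenv())

scenario <- function(name, builder) {
  hit <- .scenario_cache[[name]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  assign(name, val, envir = .scenario_cache)
  val
}

# Pseudo-3D resolution scenario: one large vessel filling during the scan,
# moderately absorbing material (delta/beta = 150) so the retrieval kernel
# is thin; used for the edge-response and edge-position tests.
res_scenario <- function() scenario("resolution", function() {
  db <- 150
  geom <- system_geometry(delta_beta = db)
  n <- 96L; nz <- 32L
  vx <- effective_pixel_size(geom)
  optics <- list(air = c(delta = 0, beta = 0),
                 wood = c(delta = 4.0e-7, beta = 4.0e-7 / db),
                 water = c(delta = 5.1e-7, beta = 5.1e-7 / db))
  ph <- build_phantom(1, c(n, n, nz), seed = 31, radius_range = c(90, 95),
                      material_optics = optics)
  z0 <- nz / 2 * vx
  speed <- 9 * vx / 9
  t_mid <- z0 / (2 * speed)
  sch <- fill_schedule(ph$vessel_table, k = z0 / sqrt(t_mid))
  timeline <- function(t) fill_state(ph, sch, t_mid - 4.5 + t)
  v <- fbp_reconstruct(retrieve_projections(
    simulate_scan(ph, reference_protocol(n_projections = 360, seed = 2), geom)))
  dyn <- simulate_scan(timeline, dynamic_protocol(n_projections = 180, seed = 3),
                       geom)
  dtv <- pdhg_reconstruct(retrieve_projections(dyn), prior_field(v),
                          recon_config())
  vt <- ph$vessel_table
  list(geom = geom, phantom = ph, v = v, dtv = dtv, vt = vt, n = n, nz = nz,
       vx = vx, ix = round(vt$x + (n + 1) / 2), iy = round(vt$y + (n + 1) / 2))
})

# Dynamic-slice scenario: textured 128^2 slice, dry reference scan and a
# wet dynamic scan (half the vessels filled), used by the alignment and
# method-level tests.
slice_scenario <- function() scenario("slice", function() {
  geom <- system_geometry()
  ph <- build_phantom(6, c(128L, 128L), seed = 21, wood_texture = 0.25)
  sch <- fill_schedule(ph$vessel_table)
  sch$t0 <- rep(c(0, 1e9), 3)
  wet <- fill_state(ph, sch, 1)
  ref <- simulate_scan(ph, reference_protocol(n_projections = 360, seed = 1), geom)
  ref_sino <- retrieve_projections(ref)
  v <- fbp_reconstruct(ref_sino)
  list(geom = geom, phantom = ph, wet = wet, ref = ref, v = v)
})
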