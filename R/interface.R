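# Run configuration and pipeline driver.  A single YAML file declares the
# geometry, phantom, scan protocols, retrieval, reconstruction and analysis
# parameters; run_pipeline() executes the staged workflow simulate ->
# retrieve -> align -> reconstruct -> analyse on the synthetic sample and
# writes a manifest of every artefact with content hashes.

#' Default run configuration
#'
#' Every stage parameter has a default; the geometry and protocol defaults
#' mirror the reference instrument configuration (R1 = 320 mm, R2 = 140 mm,
#' 70/30 um blur widths, 15 um pixels, delta/beta = 1000, continuous
#' dynamic scans at 20 deg/s with 50 ms exposures), while grid sizes and
#' projection counts are scaled to desk size.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    log_level = "info",
    geometry = list(R1 = 320, R2 = 140, sigma_s = 70, sigma_d = 30,
                    pixel_pitch = 15, lambda_eff = 6.526e-11, delta_beta = 1000),
    phantom = list(n_vessels = 6L, grid = c(64L, 64L), n_paired = 0L,
                   radius_range = c(25, 60), wood_texture = 0),
    schedule = list(t0 = 0, k_coef = 2400),
    scan = list(
      reference = list(n_projections = 180L, exposure = 1,
                       photons_per_pixel = 20000, angular_range = 360),
      dynamic = list(n_projections = 90L, exposure = 0.05,
                     angular_velocity = 20, photons_per_pixel = 1000)),
    retrieval = list(delta_beta = NULL, pad = TRUE, clamp = 1e-6),
    align = list(offset_steps = 5L, enabled = TRUE),
    recon = list(alpha = 1, eta = NULL, n_iterations = 10L, init = "fbp",
                 filter = "hann"),
    analysis = list(bins = 64L),
    waterfront = list(ratio_threshold = 0.1, persistence = 20L,
                      sweep = c(0.05, 0.15)),
    paths = list(outdir = "dtvtomo_run")
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read / write a run configuration
#'
#' YAML on disk; unknown keys are rejected and missing keys filled with
#' defaults, so `write_run_config` then `read_run_config` round-trips.
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return `read_run_config` returns a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_into <- function(base, new, crumb = "") {
    for (k in names(new)) {
      if (!k %in% names(base))
        stop("unknown config key: ", paste0(crumb, k))
      if (is.list(base[[k]]) && is.list(new[[k]]))
        base[[k]] <- merge_into(base[[k]], new[[k]], paste0(crumb, k, "."))
      else base[k] <- list(new[[k]])   # keeps explicit NULLs
    }
    base
  }
  cfg <- merge_into(unclass(cfg), raw)
  class(cfg) <- c("run_config", "list")
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_run_config <- function(cfg) {
  if (cfg$recon$alpha < 0) stop("config validation: recon.alpha must be >= 0")
  if (!is.null(cfg$recon$eta) && cfg$recon$eta <= 0)
    stop("config validation: recon.eta must be > 0")
  if (cfg$geometry$R1 <= 0) stop("config validation: geometry.R1 must be > 0")
  if (cfg$geometry$R2 < 0) stop("config validation: geometry.R2 must be >= 0")
  if (cfg$scan$dynamic$angular_velocity <= 0)
    stop("config validation: scan.dynamic.angular_velocity must be > 0")
  if (cfg$waterfront$persistence < 1)
    stop("config validation: waterfront.persistence must be >= 1")
  cfg
}

config_geometry <- function(cfg) do.call(system_geometry, cfg$geometry)

#' Run the staged pipeline on the synthetic sample
#'
#' Executes the requested stages in order on a phantom generated from the
#' configuration: `simulate` (reference and dynamic scans), `retrieve`
#' (phase retrieval to delta-path sinograms), `align` (angular offset of
#' the dynamic scan against the reference reconstruction), `reconstruct`
#' (FBP and dTV-PDHG volumes) and `analyse` (CNR summary of the vessel
#' classes).  Later stages read the artefacts written by earlier ones, so a
#' stage subset fails loudly if its inputs are missing.  A
#' `manifest.json` listing every artefact with an MD5 content hash and the
#' effective configuration is written at the end.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param stages Character subset of
#'   `c("simulate", "retrieve", "align", "reconstruct", "analyse")`.
#' @param outdir Output directory (defaults to `config$paths$outdir`).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "retrieve", "align",
                                    "reconstruct", "analyse"),
                         outdir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  config <- validate_run_config(config)
  outdir <- outdir %||% config$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  geom <- config_geometry(config)
  say <- function(...) if (identical(config$log_level, "info")) message(...)
  artefacts <- character()
  add <- function(p) artefacts <<- c(artefacts, p)

  pc <- config$phantom
  phantom <- build_phantom(pc$n_vessels, grid_shape = pc$grid,
                           voxel_size = effective_pixel_size(geom),
                           seed = config$seed, radius_range = pc$radius_range,
                           n_paired = pc$n_paired, wood_texture = pc$wood_texture)
  sch <- fill_schedule(phantom$vessel_table, t0 = config$schedule$t0,
                       k_coef = config$schedule$k_coef)
  if (phantom$grid_shape[3] == 1L) {
    # single-slice runs: half the vessels have been reached by the water
    sch$t0 <- rep(c(0, 1e12), length.out = nrow(sch))
    wet_time <- 1
  } else {
    wet_time <- (phantom$grid_shape[3] * phantom$voxel_size / (2 * max(sch$k)))^2
  }
  wet <- fill_state(phantom, sch, wet_time)

  paths <- list(ref = file.path(outdir, "reference_projections.tif"),
                dyn = file.path(outdir, "dynamic_projections.tif"),
                ref_sino = file.path(outdir, "reference_phase_sinogram.tif"),
                dyn_sino = file.path(outdir, "dynamic_phase_sinogram.tif"),
                ref_vol = file.path(outdir, "reference_volume.tif"),
                fbp_vol = file.path(outdir, "dynamic_fbp.tif"),
                dtv_vol = file.path(outdir, "dynamic_dtv.tif"),
                conv_vol = file.path(outdir, "dynamic_conventional.tif"),
                align = file.path(outdir, "alignment.json"),
                conv_log = file.path(outdir, "convergence.json"),
                metrics = file.path(outdir, "metrics.csv"))

  if ("simulate" %in% stages) {
    say("simulate: reference + dynamic scans")
    rp <- do.call(scan_protocol,
                  c(list(mode = "static"), config$scan$reference,
                    list(seed = config$seed + 11L)))
    dp <- do.call(scan_protocol,
                  c(list(mode = "continuous"), config$scan$dynamic,
                    list(seed = config$seed + 13L)))
    ref <- simulate_scan(phantom, rp, geom)
    dyn <- simulate_scan(wet, dp, geom)
    write_projections(ref, paths$ref); add(paths$ref)
    write_projections(dyn, paths$dyn); add(paths$dyn)
    write_phantom(phantom, outdir, "phantom"); add(file.path(outdir, "phantom_vessels.csv"))
    saveRDS(list(ref = ref, dyn = dyn), file.path(outdir, ".scans.rds"))
  }
  if ("retrieve" %in% stages) {
    if (!file.exists(file.path(outdir, ".scans.rds")))
      stop("stage 'retrieve': missing upstream artefact from 'simulate'")
    say("retrieve: phase retrieval")
    scans <- readRDS(file.path(outdir, ".scans.rds"))
    db <- config$retrieval$delta_beta
    ref_sino <- retrieve_projections(scans$ref, delta_beta = db,
                                     pad = config$retrieval$pad,
                                     clamp = config$retrieval$clamp)
    dyn_sino <- retrieve_projections(scans$dyn, delta_beta = db,
                                     pad = config$retrieval$pad,
                                     clamp = config$retrieval$clamp)
    write_sinogram(ref_sino, paths$ref_sino); add(paths$ref_sino)
    write_sinogram(dyn_sino, paths$dyn_sino); add(paths$dyn_sino)
    v <- fbp_reconstruct(ref_sino, filter = config$recon$filter)
    write_volume(v, paths$ref_vol); add(paths$ref_vol)
  }
  if ("align" %in% stages && isTRUE(config$align$enabled)) {
    if (!file.exists(paths$dyn_sino))
      stop("stage 'align': missing upstream artefact from 'retrieve'")
    say("align: angular offset search")
    dyn_sino <- read_sinogram(paths$dyn_sino)
    v <- read_volume(paths$ref_vol)
    step <- median(diff(sort(dyn_sino$angles)))
    grid <- seq(-config$align$offset_steps, config$align$offset_steps) * step
    al <- estimate_angular_offset(dyn_sino, v, grid)
    jsonlite::write_json(list(offset_deg = al$estimate,
                              curve = al$objective_curve, notes = al$notes),
                         paths$align, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    add(paths$align)
  }
  if ("reconstruct" %in% stages) {
    if (!file.exists(paths$dyn_sino))
      stop("stage 'reconstruct': missing upstream artefact from 'retrieve'")
    say("reconstruct: FBP + dTV-PDHG")
    dyn_sino <- read_sinogram(paths$dyn_sino)
    v <- read_volume(paths$ref_vol)
    offset <- 0
    if (file.exists(paths$align))
      offset <- jsonlite::read_json(paths$align)$offset_deg
    dyn_sino$angles <- dyn_sino$angles + offset
    fbp <- fbp_reconstruct(dyn_sino, filter = config$recon$filter)
    write_volume(fbp, paths$fbp_vol); add(paths$fbp_vol)
    scans <- readRDS(file.path(outdir, ".scans.rds"))
    conv_sino <- attenuation_sinogram(scans$dyn)
    conv_sino$angles <- conv_sino$angles + offset
    conv <- fbp_reconstruct(conv_sino, filter = config$recon$filter)
    write_volume(conv, paths$conv_vol); add(paths$conv_vol)
    rc <- recon_config(alpha = config$recon$alpha, eta = config$recon$eta,
                       n_iterations = config$recon$n_iterations,
                       init = config$recon$init, filter = config$recon$filter,
                       seed = config$seed)
    dtv <- pdhg_reconstruct(dyn_sino, prior_field(v, eta = config$recon$eta), rc)
    write_volume(dtv, paths$dtv_vol); add(paths$dtv_vol)
    jsonlite::write_json(attr(dtv, "convergence"), paths$conv_log,
                         dataframe = "columns", digits = NA)
    add(paths$conv_log)
  }
  if ("analyse" %in% stages) {
    if (!file.exists(paths$dtv_vol))
      stop("stage 'analyse': missing upstream artefact from 'reconstruct'")
    say("analyse: class CNR per reconstruction")
    masks <- phantom_masks(wet)
    core <- function(m) m & !grad_near_boundary(m)
    regions <- region_spec(air = core(masks$air), wood = core(masks$wood),
                           water = core(masks$water))
    rows <- lapply(c(conventional = paths$conv_vol,
                     analytical_pr = paths$fbp_vol,
                     regularised_pr = paths$dtv_vol), function(p) {
      vol <- read_volume(p)
      s <- material_histograms(vol, regions, bins = config$analysis$bins)$summary
      s
    })
    out <- do.call(rbind, Map(function(nm, s) cbind(reconstruction = nm, s),
                              names(rows), rows))
    cnrs <- vapply(rows, function(s)
      cnr_from_stats(s$mean[s$category == "water"], s$sd[s$category == "water"],
                     s$mean[s$category == "air"], s$sd[s$category == "air"]),
      numeric(1))
    out$cnr_water_air <- cnrs[match(out$reconstruction, names(cnrs))]
    utils::write.csv(out, paths$metrics, row.names = FALSE)
    add(paths$metrics)
  }

  manifest <- list(
    package = "dtvtomo",
    seed = config$seed,
    stages = stages,
    config = unclass(config),
    artefacts = lapply(sort(unique(artefacts)), function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)),
           bytes = file.size(p)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# erode a mask by one voxel in-plane so region statistics avoid partial-volume
# boundary voxels
grad_near_boundary <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    mm <- m[, , z]
    nb <- mm[c(1, seq_len(d[1] - 1)), ] & mm[c(seq_len(d[1] - 1) + 1, d[1]), ] &
      mm[, c(1, seq_len(d[2] - 1))] & mm[, c(seq_len(d[2] - 1) + 1, d[2])]
    out[, , z] <- !nb
  }
  out & m
}
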