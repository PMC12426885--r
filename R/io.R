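# File I/O: volumes and projection sets as multi-page 32-bit-float TIFF
# stacks with JSON/CSV sidecars carrying value ranges, voxel sizes, angles
# and timestamps.  TIFF stores values scaled to [0, 1]; the sidecar records
# the affine range so the round trip is lossless to 32-bit float precision.

tiff_pack <- function(a) {
  rng <- range(a)
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  list(pages = lapply(seq_len(dim(a)[3]),
                      function(z) matrix((a[, , z] - rng[1]) / diff(rng),
                                         dim(a)[1], dim(a)[2])),
       range = rng)
}

tiff_unpack <- function(pages, rng) {
  a <- array(0, c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) a[, , z] <- pages[[z]] * diff(rng) + rng[1]
  a
}

#' Write / read a volume image as a TIFF stack
#'
#' One page per axial slice, 32-bit float, with a JSON sidecar
#' (`<path>.json`) holding the value range, voxel size and semantics.
#'
#' @param volume A [volume_image()].
#' @param path Output `.tif` path.
#' @return `write_volume` returns the path invisibly; `read_volume` a
#'   [volume_image()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  if (!grepl("\\.tiff?$", path)) stop("unknown extension (expected .tif/.tiff): ", path)
  pk <- tiff_pack(volume$values)
  tiff::writeTIFF(pk$pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(range = pk$range, voxel_size = volume$voxel_size,
               semantics = volume$semantics, dim = dim(volume$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar metadata: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$dim[3]) stop("slice count mismatch with sidecar")
  volume_image(tiff_unpack(pages, meta$range), voxel_size = meta$voxel_size,
               semantics = meta$semantics)
}

#' Write / read a projection set as TIFF + CSV sidecar
#'
#' Projections are stored one per page (32-bit float, shared scaling with
#' flat and dark appended as the final two pages); the CSV sidecar carries
#' per-projection angles and timestamps and the JSON sidecar the scan
#' scalars.
#'
#' @param pset A [simulate_scan()] result.
#' @param path Output `.tif` path.
#' @return `write_projections` returns the path invisibly;
#'   `read_projections` a `projection_set`-like list (without the protocol
#'   closure).
#' @export
write_projections <- function(pset, path) {
  if (!grepl("\\.tiff?$", path)) stop("unknown extension (expected .tif/.tiff): ", path)
  d <- dim(pset$intensity)
  stack <- array(0, c(d[1], d[2], d[3] + 2L))
  stack[, , seq_len(d[3])] <- pset$intensity
  stack[, , d[3] + 1L] <- pset$flat
  stack[, , d[3] + 2L] <- pset$dark
  pk <- tiff_pack(stack)
  tiff::writeTIFF(pk$pages, path, bits.per.sample = 32L, reduce = FALSE)
  utils::write.csv(data.frame(index = seq_len(d[3]), angle = pset$angles,
                              timestamp = pset$timestamps),
                   paste0(path, ".csv"), row.names = FALSE)
  meta <- list(range = pk$range, dim = d, voxel_size = pset$voxel_size)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  side <- paste0(path, ".json"); csv <- paste0(path, ".csv")
  if (!file.exists(side)) stop("missing sidecar metadata: ", side)
  if (!file.exists(csv)) stop("missing angle/timestamp sidecar: ", csv)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  tb <- utils::read.csv(csv)
  if (!all(c("angle", "timestamp") %in% names(tb)))
    stop("sidecar lacks angle/timestamp columns")
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- tiff_unpack(pages, meta$range)
  d <- meta$dim
  if (length(pages) != d[3] + 2L) stop("page count mismatch with sidecar")
  structure(list(intensity = stack[, , seq_len(d[3]), drop = FALSE],
                 flat = stack[, , d[3] + 1L], dark = stack[, , d[3] + 2L],
                 angles = tb$angle, timestamps = tb$timestamp,
                 voxel_size = meta$voxel_size),
            class = "projection_set")
}

#' Write / read a sinogram as TIFF + CSV sidecar
#'
#' One page per slice (rows = angles), with angles/timestamps in a CSV
#' sidecar and scalars in a JSON sidecar.
#'
#' @param sino A [sinogram()].
#' @param path Output `.tif` path.
#' @return `write_sinogram` returns the path invisibly; `read_sinogram` a
#'   [sinogram()].
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  if (!grepl("\\.tiff?$", path)) stop("unknown extension (expected .tif/.tiff): ", path)
  pk <- tiff_pack(sino$data)
  tiff::writeTIFF(pk$pages, path, bits.per.sample = 32L, reduce = FALSE)
  utils::write.csv(data.frame(index = seq_along(sino$angles), angle = sino$angles,
                              timestamp = sino$timestamps),
                   paste0(path, ".csv"), row.names = FALSE)
  meta <- list(range = pk$range, dim = dim(sino$data),
               pixel_size = sino$pixel_size, kind = sino$kind)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  side <- paste0(path, ".json"); csv <- paste0(path, ".csv")
  if (!file.exists(side)) stop("missing sidecar metadata: ", side)
  if (!file.exists(csv)) stop("missing angle/timestamp sidecar: ", csv)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  tb <- utils::read.csv(csv)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sinogram(tiff_unpack(pages, meta$range), tb$angle,
           pixel_size = meta$pixel_size, timestamps = tb$timestamp,
           kind = meta$kind)
}

#' Export a phantom's vessel table and label map
#'
#' Writes the vessel table as CSV and the material label volume as a TIFF
#' stack.
#'
#' @param phantom A [build_phantom()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the written paths.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(prefix, "_vessels.csv"))
  utils::write.csv(phantom$vessel_table, csv, row.names = FALSE)
  tif <- file.path(dir, paste0(prefix, "_labels.tif"))
  write_volume(volume_image(phantom$labels + 0, voxel_size = phantom$voxel_size,
                            semantics = "delta"), tif)
  invisible(c(csv, tif))
}
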