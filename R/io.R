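#' Write / read a channel image as TIFF with a JSON metadata sidecar
#'
#' Intensities are stored as 32-bit float TIFF scaled into \[0, 1\] by the
#' image maximum; the sidecar (`<path>.json`) records the scale together
#' with the channel, marker, exposure and pixel-size metadata so the reader
#' can restore intensities and metadata. Precision is that of 32-bit float.
#'
#' @param ci a [channel_image()].
#' @param path output TIFF path.
#' @return The path, invisibly.
#' @export
write_channel_tiff <- function(ci, path) {
  # power-of-two scale: division is a pure exponent shift, so float32
  # values written once round-trip exactly on every later cycle
  scale <- pow2_scale(max(ci$pixels))
  tiff::writeTIFF(ci$pixels / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = scale, channel = ci$channel,
                            marker = ci$marker, exposure_ms = ci$exposure_ms,
                            pixel_size_um = ci$pixel_size_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_channel_tiff
#' @export
read_channel_tiff <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  if (!file.exists(side)) stop("missing metadata sidecar: ", side,
                               call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * meta$scale
  channel_image(px, meta$channel, meta$marker, meta$exposure_ms,
                meta$pixel_size_um)
}

#' Write / read a DTA map as 32-bit float TIFF plus JSON sidecar
#'
#' The map is affinely scaled into \[0, 1\] (invalid pixels stored as 0 and
#' recorded in the sidecar-referenced validity mask file `<path>.valid.tif`);
#' the sidecar records `lo`, `hi`, `sf_used` and `floor_eps`.
#'
#' @param map a [compute_dta_map()] result.
#' @param path output TIFF path.
#' @return The path, invisibly.
#' @export
write_dta_tiff <- function(map, path) {
  v <- map$dta
  vv <- v[map$valid]
  lo <- if (length(vv)) min(vv) else 0
  hi <- if (length(vv)) max(vv) else 1
  # power-of-two offset and scale keep the [0,1] mapping exactly invertible
  # in double arithmetic, so repeated write/read cycles are stable
  offset <- if (lo < 0) pow2_scale(-lo) else 0
  scale <- pow2_scale(hi + offset)
  scaled <- matrix(0, nrow(v), ncol(v))
  scaled[map$valid] <- (vv + offset) / scale
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  tiff::writeTIFF((map$valid * 1), paste0(path, ".valid.tif"),
                  bits.per.sample = 8L)
  jsonlite::write_json(list(offset = offset, scale = scale,
                            sf_used = map$sf_used,
                            floor_eps = map$floor_eps),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# smallest power of two >= x (and >= 1)
pow2_scale <- function(x) 2^max(0, ceiling(log2(max(x, .Machine$double.eps))))

#' @rdname write_dta_tiff
#' @export
read_dta_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  scaled <- tiff::readTIFF(path)
  valid <- tiff::readTIFF(paste0(path, ".valid.tif")) > 0
  dta <- matrix(NA_real_, nrow(scaled), ncol(scaled))
  dta[valid] <- scaled[valid] * meta$scale - meta$offset
  structure(list(dta = dta, valid = valid, sf_used = meta$sf_used,
                 floor_eps = meta$floor_eps),
            class = "dta_map")
}

#' Write / read a label image as 16-bit TIFF
#'
#' Integer labels up to 65535 round-trip exactly.
#' @param labels a [segment_nuclei()] result.
#' @param path output TIFF path.
#' @return The path, invisibly.
#' @export
write_labels_tiff <- function(labels, path) {
  if (labels$n_cells > 65535L)
    stop("more than 65535 labels cannot be stored in 16-bit TIFF",
         call. = FALSE)
  tiff::writeTIFF(labels$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  lab <- round(tiff::readTIFF(path) * 65535)
  storage.mode(lab) <- "integer"
  structure(list(labels = lab, n_cells = max(lab)), class = "label_image")
}

#' Write / read a tissue mask as 8-bit TIFF
#' @param mask a [make_tissue_mask()] result.
#' @param path output TIFF path.
#' @return The path, invisibly; reading returns a `tissue_mask` with
#'   provenance `"imported"`.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask$mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path) > 0
  structure(list(mask = m, provenance = "imported", threshold = NA_real_),
            class = "tissue_mask")
}

#' Write / read a cell table as CSV
#'
#' Column order and formatting are fixed so identical tables produce
#' byte-identical files; the intensity/wavelength/exposure attributes are
#' stored in a JSON sidecar and restored on read.
#'
#' @param cells a cell table.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  meta <- list(intensity_cols = attr(cells, "intensity_cols"),
               wavelengths = as.list(attr(cells, "wavelengths")),
               exposures = as.list(attr(cells, "exposures")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(df, "intensity_cols") <- meta$intensity_cols
    attr(df, "wavelengths") <- unlist(meta$wavelengths)
    attr(df, "exposures") <- unlist(meta$exposures)
  }
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Write a phantom to disk as TIFFs plus truth CSV and config YAML
#'
#' One TIFF (with sidecar) per round/channel under `dir/<round>_<marker>.tif`,
#' the truth table as `truth.csv`, the round manifest as `manifest.yaml`.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(rounds = list())
  for (rn in names(phantom$rounds)) {
    chans <- list()
    for (mk in names(phantom$rounds[[rn]])) {
      ci <- phantom$rounds[[rn]][[mk]]
      fn <- sprintf("%s_%s.tif", rn, gsub("[^A-Za-z0-9_-]", "-", mk))
      write_channel_tiff(ci, file.path(dir, fn))
      chans[[mk]] <- list(path = fn, marker = mk, wavelength = ci$channel,
                          exposure_ms = ci$exposure_ms)
    }
    manifest$rounds[[rn]] <- chans
  }
  utils::write.csv(phantom$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  mpath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Load a multi-round channel stack from a manifest
#'
#' The YAML manifest lists, per round, each channel's file path, marker,
#' wavelength and exposure. Validation checks every file exists, every
#' channel has a positive exposure, and all images share one shape.
#'
#' @param manifest path to a manifest YAML (as written by [write_phantom()]),
#'   or an equivalent list.
#' @param base_dir directory paths are relative to; defaults to the
#'   manifest's directory.
#' @return A named list of rounds, each a named list of [channel_image()]s.
#' @export
load_stack <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- yaml::read_yaml(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  if (is.null(manifest$rounds) || length(manifest$rounds) == 0L)
    stop("manifest has no rounds", call. = FALSE)
  shape <- NULL
  rounds <- list()
  for (rn in names(manifest$rounds)) {
    chans <- list()
    for (mk in names(manifest$rounds[[rn]])) {
      entry <- manifest$rounds[[rn]][[mk]]
      p <- file.path(base_dir, entry$path)
      if (!file.exists(p))
        stop("manifest references a missing file: ", p, call. = FALSE)
      if (is.null(entry$exposure_ms) || entry$exposure_ms <= 0)
        stop("channel `", mk, "` in round `", rn,
             "` lacks a positive exposure_ms", call. = FALSE)
      ci <- read_channel_tiff(p)
      ci$marker <- entry$marker %||% mk
      ci$channel <- entry$wavelength %||% ci$channel
      ci$exposure_ms <- entry$exposure_ms
      if (is.null(shape)) shape <- dim(ci$pixels)
      if (!identical(dim(ci$pixels), shape))
        stop("shape mismatch in round `", rn, "`, channel `", mk, "`",
             call. = FALSE)
      chans[[mk]] <- ci
    }
    rounds[[rn]] <- chans
  }
  rounds
}

`%||%` <- function(a, b) if (is.null(a)) b else a
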