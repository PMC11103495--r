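#' Single-channel fluorescence image with acquisition metadata
#'
#' A `channel_image` wraps one 2D matrix of nonnegative intensities together
#' with the metadata the downstream pipeline needs: the filter/wavelength tag
#' (DAPI, Cy2, Cy3, Cy5, Cy7), the marker or probe imaged in that channel,
#' the exposure time used to acquire it, and the pixel size.
#'
#' @param pixels numeric matrix of finite, nonnegative intensities (a.u.).
#' @param channel wavelength tag, e.g. `"DAPI"`, `"Cy2"`, `"Cy3"`, `"Cy5"`,
#'   `"Cy7"`.
#' @param marker marker or probe label imaged in this channel; defaults to
#'   the wavelength tag.
#' @param exposure_ms exposure time in milliseconds (> 0).
#' @param pixel_size_um physical pixel size in micrometres.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel, marker = channel,
                          exposure_ms = 1, pixel_size_um = 1) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a nonempty numeric matrix", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("`pixels` must be finite everywhere", call. = FALSE)
  if (any(pixels < 0))
    stop("`pixels` must be nonnegative", call. = FALSE)
  if (!is.numeric(exposure_ms) || length(exposure_ms) != 1L || exposure_ms <= 0)
    stop("`exposure_ms` must be a single positive number", call. = FALSE)
  structure(
    list(pixels = pixels, channel = as.character(channel),
         marker = as.character(marker), exposure_ms = as.numeric(exposure_ms),
         pixel_size_um = as.numeric(pixel_size_um)),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s (%s), %d x %d px, exposure %g ms\n",
              x$marker, x$channel, nrow(x$pixels), ncol(x$pixels),
              x$exposure_ms))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

# Accept either a channel_image or a bare matrix; return the pixel matrix.
as_pixels <- function(x) {
  if (inherits(x, "channel_image")) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a channel_image or a numeric matrix", call. = FALSE)
}
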