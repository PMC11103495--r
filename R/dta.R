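#' Build a tissue mask from a reference channel
#'
#' Replaces manual tissue outlining: thresholds the reference image (Otsu by
#' default), keeps the largest connected foreground component and fills its
#' holes. An externally drawn mask can be passed through unchanged with
#' provenance `"imported"`.
#'
#' @param reference a [channel_image()] or numeric matrix used to find
#'   tissue (typically the untargeted-probe or an autofluorescence channel).
#' @param method `"otsu"` or `"threshold"` (then supply `value`).
#' @param value fixed threshold when `method = "threshold"`.
#' @param imported optional logical matrix: an externally drawn mask returned
#'   as-is.
#' @return A list of class `tissue_mask`: `mask` (logical matrix),
#'   `provenance` (`"automatic"` or `"imported"`), `threshold`.
#' @export
make_tissue_mask <- function(reference, method = c("otsu", "threshold"),
                             value = NULL, imported = NULL) {
  if (!is.null(imported)) {
    m <- imported
    if (is.numeric(m)) m <- m > 0
    if (!is.matrix(m) || !is.logical(m))
      stop("`imported` must be a logical matrix", call. = FALSE)
    if (!any(m)) stop("imported mask is empty", call. = FALSE)
    return(structure(list(mask = m, provenance = "imported", threshold = NA_real_),
                     class = "tissue_mask"))
  }
  method <- match.arg(method)
  px <- as_pixels(reference)
  hi <- max(px)
  if (hi <= 0) stop("no tissue found: reference image is empty", call. = FALSE)
  thr <- if (method == "otsu") {
    # Otsu in the log domain: tissue sections have slide background, dim
    # tissue matrix and bright cells; a linear-scale Otsu splits off only
    # the bright cells, while log intensities separate slide vs tissue.
    lpx <- log1p(px)
    lhi <- max(lpx)
    expm1(EBImage::otsu(EBImage::Image(lpx / lhi), range = c(0, 1)) * lhi)
  } else {
    if (is.null(value)) stop("`value` required for fixed threshold", call. = FALSE)
    value
  }
  fg <- px > thr
  if (!any(fg)) stop("no tissue found: threshold removes every pixel", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  m <- lab == keep
  m <- EBImage::imageData(EBImage::fillHull(EBImage::Image(m * 1))) > 0
  structure(list(mask = m, provenance = "automatic", threshold = unname(thr)),
            class = "tissue_mask")
}

#' Compute the per-pixel drug-target-availability (DTA) map
#'
#' For every masked pixel whose untargeted intensity exceeds `floor_eps`,
#' \deqn{DTA = SF \cdot I_T / I_{UnT} - 1}
#' where \eqn{SF} (the slope ratio untargeted/targeted from titration) puts
#' both channels on a common concentration-equivalent scale; the untargeted
#' probe reports nonspecific uptake, so the ratio minus one is the specific
#' (bound) excess — a binding-potential-style readout that drops when the
#' unlabeled parent drug occupies the target. Pixels failing the denominator
#' floor or outside the mask are marked invalid and excluded from all
#' summaries. Values are not clipped; negative DTA is retained.
#'
#' An alternative convention placing the scaling on the untargeted channel
#' (`sf_on = "untargeted"`: `DTA = I_T / (SF * I_UnT) - 1`) is available for
#' calibrations defined as the inverse slope ratio.
#'
#' @param targeted,untargeted [channel_image()]s (or matrices) of identical
#'   shape.
#' @param sf a [compute_scaling_factor()] result, or a single positive
#'   number.
#' @param mask optional [make_tissue_mask()] result; default all pixels.
#' @param floor_eps minimum untargeted intensity for a defined ratio
#'   (default a small positive constant; see [floor_from_reference()]).
#' @param sf_on `"targeted"` (default) or `"untargeted"`.
#' @return A list of class `dta_map`: `dta` (matrix, `NA` where invalid),
#'   `valid` (logical matrix), `sf_used`, `floor_eps`.
#' @export
compute_dta_map <- function(targeted, untargeted, sf, mask = NULL,
                            floor_eps = 1e-6,
                            sf_on = c("targeted", "untargeted")) {
  sf_on <- match.arg(sf_on)
  it <- as_pixels(targeted); iu <- as_pixels(untargeted)
  if (!identical(dim(it), dim(iu)))
    stop("targeted and untargeted images differ in shape", call. = FALSE)
  sfv <- if (inherits(sf, "scaling_factor")) sf$sf else as.numeric(sf)
  if (length(sfv) != 1L || !is.finite(sfv) || sfv <= 0)
    stop("scaling factor must be a single positive number", call. = FALSE)
  if (floor_eps < 0) stop("`floor_eps` must be nonnegative", call. = FALSE)
  m <- if (is.null(mask)) matrix(TRUE, nrow(it), ncol(it)) else mask$mask
  if (!identical(dim(m), dim(it)))
    stop("mask shape does not match the images", call. = FALSE)
  valid <- m & (iu > floor_eps)
  dta <- matrix(NA_real_, nrow(it), ncol(it))
  dta[valid] <- if (sf_on == "targeted") sfv * it[valid] / iu[valid] - 1
                else it[valid] / (sfv * iu[valid]) - 1
  structure(list(dta = dta, valid = valid, sf_used = sfv,
                 floor_eps = floor_eps),
            class = "dta_map")
}

#' Denominator floor from a reference (vehicle / autofluorescence) image
#'
#' Returns the 95th percentile (configurable) of a reference image, used as
#' `floor_eps` so that ratios are never formed against denominators at
#' autofluorescence level.
#'
#' @param reference [channel_image()] or matrix.
#' @param q quantile in (0, 1), default 0.95.
#' @return A single number.
#' @export
floor_from_reference <- function(reference, q = 0.95) {
  unname(stats::quantile(as_pixels(reference), q, type = 7))
}

#' Summarize an image or DTA map over a tissue mask
#'
#' Mean, median, lower/upper quartile and pixel count over the masked pixels;
#' for a DTA map only valid pixels contribute.
#'
#' @param x a [channel_image()], numeric matrix or `dta_map`.
#' @param mask a [make_tissue_mask()] result (or logical matrix).
#' @return A list: `mean`, `median`, `q25`, `q75`, `n_pixels`.
#' @export
summarize_region <- function(x, mask) {
  m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  if (!any(m)) stop("mask selects no pixels", call. = FALSE)
  vals <- if (inherits(x, "dta_map")) {
    if (!identical(dim(x$dta), dim(m))) stop("shape mismatch", call. = FALSE)
    x$dta[m & x$valid]
  } else {
    px <- as_pixels(x)
    if (!identical(dim(px), dim(m))) stop("shape mismatch", call. = FALSE)
    px[m]
  }
  if (length(vals) == 0L)
    stop("no valid pixels under the mask", call. = FALSE)
  qs <- unname(stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7))
  list(mean = mean(vals), median = qs[2], q25 = qs[1], q75 = qs[3],
       n_pixels = length(vals))
}
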