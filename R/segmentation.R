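#' Segment nuclei from a DAPI channel
#'
#' Otsu threshold, hole filling, then a distance-transform watershed to
#' split touching nuclei. Components smaller than `min_area_px` are
#' discarded and the surviving labels renumbered contiguously `1..n_cells`.
#' A blank image yields zero cells with a warning rather than an error.
#'
#' @param dapi [channel_image()] or numeric matrix.
#' @param min_area_px minimum nuclear area (px) to keep.
#' @param tolerance,ext watershed parameters (see [EBImage::watershed()]);
#'   the defaults split disks touching at a single boundary.
#' @return A list of class `label_image`: `labels` (integer matrix, 0 =
#'   background), `n_cells`.
#' @export
segment_nuclei <- function(dapi, min_area_px = 20, tolerance = 1, ext = 1) {
  px <- as_pixels(dapi)
  hi <- max(px)
  empty <- function() {
    warning("blank DAPI image: no nuclei segmented", call. = FALSE)
    structure(list(labels = matrix(0L, nrow(px), ncol(px)), n_cells = 0L),
              class = "label_image")
  }
  if (hi <= 0) return(empty())
  thr <- EBImage::otsu(EBImage::Image(px / hi), range = c(0, 1)) * hi
  bw <- px > thr
  if (!any(bw)) return(empty())
  bw <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
  dm <- EBImage::distmap(EBImage::Image(bw * 1))
  wl <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance,
                                              ext = ext))
  sizes <- tabulate(wl[wl > 0])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0L) return(empty())
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  lab <- matrix(0L, nrow(px), ncol(px))
  nz <- wl > 0
  lab[nz] <- remap[wl[nz]]
  structure(list(labels = lab, n_cells = length(keep)),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %d cells, %d x %d px\n", x$n_cells,
              nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

# Expand nuclear labels by `px` pixels; ring pixels contested by several
# cells go to the nearest nucleus (geodesic Voronoi growth), so a cell's
# expanded region never reaches past a closer neighboring nucleus.
expand_labels <- function(lab, px) {
  if (px <= 0 || max(lab) == 0L) return(lab)
  brush <- EBImage::makeBrush(2L * as.integer(px) + 1L, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image((lab > 0) * 1),
                                            brush)) > 0
  grown <- EBImage::propagate(EBImage::Image(matrix(0, nrow(lab), ncol(lab))),
                              seeds = EBImage::Image(lab), mask = dil,
                              lambda = 1e50)
  out <- EBImage::imageData(grown)
  storage.mode(out) <- "integer"
  out
}

#' Extract per-cell features from a registered channel stack
#'
#' For every cell: nuclear area and centroid from the label mask; per-channel
#' mean intensity over the nuclear mask dilated by `cell_expansion_px`
#' (cytoplasmic capture, contested pixels to the nearest nucleus);
#' and, if a DTA map is supplied, the mean of its valid pixels in the
#' expanded mask together with the valid-pixel fraction (cells with no valid
#' DTA pixel get `NA` and fraction 0).
#'
#' @param labels a [segment_nuclei()] result.
#' @param stack named list of [channel_image()]s, registered to the label
#'   grid; names are marker ids (autofluorescence channels as `"AF_<wl>"`).
#' @param dta optional [compute_dta_map()] result on the same grid.
#' @param cell_expansion_px ring width (px) around each nucleus.
#' @param cohort cohort/treatment label stamped on every row.
#' @return A data frame of class `cell_table`, one row per cell, with
#'   attributes `intensity_cols`, `wavelengths` (marker -> wavelength) and
#'   `exposures` (marker -> ms) taken from the stack metadata.
#' @export
extract_features <- function(labels, stack, dta = NULL,
                             cell_expansion_px = 3, cohort = NA_character_) {
  stopifnot(inherits(labels, "label_image"))
  lab <- labels$labels
  n <- labels$n_cells
  for (nm in names(stack))
    if (!identical(dim(as_pixels(stack[[nm]])), dim(lab)))
      stop("channel `", nm, "` shape does not match the label image",
           call. = FALSE)
  if (!is.null(dta) && !identical(dim(dta$dta), dim(lab)))
    stop("DTA map shape does not match the label image", call. = FALSE)

  if (n == 0L) {
    out <- data.frame(cell_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), nuclear_size = numeric(0))
    for (nm in names(stack)) out[[nm]] <- numeric(0)
    out$dta <- numeric(0); out$dta_valid_frac <- numeric(0)
    out$cohort <- character(0)
    class(out) <- c("cell_table", "data.frame")
    return(out)
  }

  fg <- lab > 0L
  ids <- lab[fg]
  area <- tabulate(ids, nbins = n)
  nr <- nrow(lab)
  lin <- which(fg)
  pr <- (lin - 1L) %% nr
  pc <- (lin - 1L) %/% nr
  cent_r <- rowsum(pr, ids)[, 1] / area
  cent_c <- rowsum(pc, ids)[, 1] / area
  centroids <- cbind(cent_r, cent_c)

  ex <- expand_labels(lab, cell_expansion_px)
  exfg <- ex > 0L
  exids <- ex[exfg]
  exn <- tabulate(exids, nbins = n)

  out <- data.frame(cell_id = seq_len(n), centroid_row = cent_r,
                    centroid_col = cent_c, nuclear_size = area)
  for (nm in names(stack)) {
    v <- as_pixels(stack[[nm]])[exfg]
    out[[nm]] <- rowsum(v, exids)[, 1] / exn
  }
  if (!is.null(dta)) {
    dv <- dta$dta[exfg]
    ok <- dta$valid[exfg]
    sums <- rowsum(ifelse(ok, dv, 0), exids)[, 1]
    nvalid <- rowsum(as.numeric(ok), exids)[, 1]
    out$dta <- ifelse(nvalid > 0, sums / nvalid, NA_real_)
    out$dta_valid_frac <- nvalid / exn
  } else {
    out$dta <- NA_real_
    out$dta_valid_frac <- 0
  }
  out$cohort <- cohort
  attr(out, "intensity_cols") <- names(stack)
  attr(out, "wavelengths") <- vapply(stack, function(ci) ci$channel, "")
  attr(out, "exposures") <- vapply(stack, function(ci) ci$exposure_ms, 0)
  class(out) <- c("cell_table", "data.frame")
  out
}
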