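#' QC / normalization settings for a cell table
#'
#' Collects the tunables of the single-cell QC chain: which autofluorescence
#' channel drives outlier removal and at what quantile, the nuclear-size
#' quantile window, the epithelial gate markers and thresholding method, and
#' the cohort label of the untreated control tissues that anchors z-scoring.
#'
#' @param af_channel autofluorescence column used for outlier removal.
#' @param af_quantile cells strictly above this quantile of `af_channel` are
#'   removed.
#' @param size_quantiles `c(low, high)`: cells with nuclear size strictly
#'   below/above these quantiles are removed.
#' @param epithelial_markers markers that must both be positive for a cell
#'   to be kept as epithelial.
#' @param gate_method `"otsu"` (threshold found on log1p-transformed values
#'   across the cohort) or `"fixed"` (then supply `gate_thresholds`).
#' @param gate_thresholds named per-marker thresholds for
#'   `gate_method = "fixed"`.
#' @param control_label cohort tag of the untreated control tissues.
#' @return A list of class `normalization_spec`.
#' @export
normalization_spec <- function(af_channel = "AF_Cy3", af_quantile = 0.95,
                               size_quantiles = c(0.05, 0.95),
                               epithelial_markers = c("CK8", "E-Cad"),
                               gate_method = c("otsu", "fixed"),
                               gate_thresholds = NULL,
                               control_label = "control") {
  gate_method <- match.arg(gate_method)
  if (af_quantile <= 0 || af_quantile >= 1)
    stop("`af_quantile` must be in (0, 1)", call. = FALSE)
  if (length(size_quantiles) != 2L || any(size_quantiles <= 0) ||
      any(size_quantiles >= 1) || size_quantiles[1] >= size_quantiles[2])
    stop("`size_quantiles` must be (low, high) fractions in (0, 1), low < high",
         call. = FALSE)
  if (gate_method == "fixed" && is.null(gate_thresholds))
    stop("`gate_thresholds` required for fixed gating", call. = FALSE)
  structure(list(af_channel = af_channel, af_quantile = af_quantile,
                 size_quantiles = size_quantiles,
                 epithelial_markers = epithelial_markers,
                 gate_method = gate_method, gate_thresholds = gate_thresholds,
                 control_label = control_label),
            class = "normalization_spec")
}

intensity_cols <- function(cells) {
  ic <- attr(cells, "intensity_cols")
  if (is.null(ic))
    stop("cell table lacks the `intensity_cols` attribute", call. = FALSE)
  ic
}

marker_cols <- function(cells) {
  ic <- intensity_cols(cells)
  ic[!startsWith(ic, "AF_") & ic != "DAPI"]
}

# carry cell_table attributes through a transformation
keep_attrs <- function(out, cells) {
  for (a in c("intensity_cols", "wavelengths", "exposures"))
    attr(out, a) <- attr(cells, a)
  class(out) <- unique(c("cell_table", class(out)))
  out
}

#' Normalize intensities by exposure time
#'
#' Divides every marker and autofluorescence mean intensity by the exposure
#' time (ms) of the channel it was imaged in, putting all intensities in
#' a.u./ms so channels acquired at different exposures are comparable.
#'
#' @param cells a [extract_features()] cell table.
#' @param exposures named per-column exposure times (ms); defaults to the
#'   `exposures` attribute stamped by [extract_features()].
#' @return The cell table with intensity columns rescaled.
#' @export
normalize_exposure <- function(cells, exposures = NULL) {
  if (is.null(exposures)) exposures <- attr(cells, "exposures")
  ic <- intensity_cols(cells)
  missing <- setdiff(ic, names(exposures))
  if (length(missing))
    stop("no exposure time for column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(exposures[ic] <= 0) || any(!is.finite(exposures[ic])))
    stop("exposure times must be positive", call. = FALSE)
  out <- cells
  for (col in ic) out[[col]] <- out[[col]] / exposures[[col]]
  keep_attrs(out, cells)
}

#' Subtract same-wavelength autofluorescence per cell
#'
#' Each marker value has the same cell's autofluorescence mean for the
#' wavelength the marker was imaged in subtracted from it. Negative
#' corrected values are retained, not clipped. Apply after
#' [normalize_exposure()] so both terms are in a.u./ms.
#'
#' @param cells a cell table.
#' @param wavelength_map named marker -> wavelength vector; defaults to the
#'   `wavelengths` attribute.
#' @return The cell table with marker columns AF-corrected.
#' @export
subtract_autofluorescence <- function(cells, wavelength_map = NULL) {
  if (is.null(wavelength_map)) wavelength_map <- attr(cells, "wavelengths")
  out <- cells
  for (col in marker_cols(cells)) {
    wl <- wavelength_map[[col]]
    if (is.null(wl) || is.na(wl))
      stop("marker `", col, "` has no wavelength mapping", call. = FALSE)
    af_col <- paste0("AF_", wl)
    if (!af_col %in% names(cells))
      stop("no autofluorescence column `", af_col, "` for marker `", col,
           "`", call. = FALSE)
    out[[col]] <- out[[col]] - out[[af_col]]
  }
  keep_attrs(out, cells)
}

#' Remove autofluorescence and nuclear-size outliers
#'
#' Thresholds are computed once on the input table using linear-interpolation
#' quantiles: cells strictly above the autofluorescence quantile are removed
#' (likely tissue artifacts), and cells with nuclear size strictly below the
#' low or strictly above the high size quantile are removed (likely
#' mis-segmented nuclei in a tissue of similarly sized cells). Removals are
#' recorded in the attached QC report.
#'
#' @param cells a cell table with the AF column and `nuclear_size`.
#' @param spec a [normalization_spec()].
#' @return The filtered cell table; attribute `"qc_report"` holds the
#'   thresholds, per-rule counts and the flags of removed cells.
#' @export
filter_outliers <- function(cells, spec = normalization_spec()) {
  if (nrow(cells) == 0L) stop("empty cell table", call. = FALSE)
  if (!spec$af_channel %in% names(cells))
    stop("AF column `", spec$af_channel, "` not in table", call. = FALSE)
  af <- cells[[spec$af_channel]]
  size <- cells$nuclear_size
  af_thr <- unname(stats::quantile(af, spec$af_quantile, type = 7))
  sz <- unname(stats::quantile(size, spec$size_quantiles, type = 7))
  af_out <- af > af_thr
  size_out <- size < sz[1] | size > sz[2]
  keep <- !af_out & !size_out
  out <- cells[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- list(af_channel = spec$af_channel, af_threshold = af_thr,
                 size_low = sz[1], size_high = sz[2],
                 n_input = nrow(cells), n_removed_af = sum(af_out),
                 n_removed_size = sum(size_out),
                 n_removed = sum(!keep), n_kept = sum(keep),
                 flags = data.frame(cell_id = cells$cell_id,
                                    af_outlier = af_out,
                                    size_outlier = size_out))
  out <- keep_attrs(out, cells)
  attr(out, "qc_report") <- report
  out
}

# 1D Otsu threshold: maximize between-class variance on a binned histogram;
# returns the bin-edge threshold.
otsu_1d <- function(v, levels = 256L) {
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps) return(hi)
  br <- seq(lo, hi, length.out = levels + 1L)
  h <- hist(v, breaks = br, plot = FALSE)$counts
  w1 <- cumsum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  m1 <- cumsum(h * mids)
  total <- w1[levels]; mt <- m1[levels]
  w2 <- total - w1
  between <- ifelse(w1 > 0 & w2 > 0,
                    (mt * w1 - m1 * total)^2 / (w1 * w2), 0)
  br[which.max(between) + 1L]
}

#' Gate cells on epithelial marker positivity
#'
#' Retains only cells positive for every epithelial marker (default CK8 and
#' E-Cadherin), isolating xenograft tumor cells from stroma. Positivity
#' thresholds come from Otsu on the log1p-transformed values across the
#' cohort, or from fixed per-marker thresholds.
#'
#' @param cells an AF-corrected cell table.
#' @param spec a [normalization_spec()].
#' @return The gated cell table; attribute `"gate_report"` records the
#'   thresholds and per-marker positive counts.
#' @export
gate_epithelial <- function(cells, spec = normalization_spec()) {
  mk <- spec$epithelial_markers
  missing <- setdiff(mk, names(cells))
  if (length(missing))
    stop("epithelial marker column(s) missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  thr <- numeric(length(mk)); names(thr) <- mk
  pos <- rep(TRUE, nrow(cells))
  n_pos <- integer(length(mk)); names(n_pos) <- mk
  for (m in mk) {
    if (spec$gate_method == "fixed") {
      if (!m %in% names(spec$gate_thresholds))
        stop("no fixed threshold for marker `", m, "`", call. = FALSE)
      thr[m] <- spec$gate_thresholds[[m]]
    } else {
      v <- cells[[m]]
      thr[m] <- expm1(otsu_1d(log1p(pmax(v, 0))))
    }
    p <- cells[[m]] > thr[m]
    n_pos[m] <- sum(p)
    pos <- pos & p
  }
  if (!any(pos))
    stop("epithelial gate removed every cell (thresholds: ",
         paste(sprintf("%s=%.4g", mk, thr), collapse = ", "),
         "; positives per marker: ",
         paste(sprintf("%s=%d", mk, n_pos), collapse = ", "), ")",
         call. = FALSE)
  out <- cells[pos, , drop = FALSE]
  rownames(out) <- NULL
  out <- keep_attrs(out, cells)
  attr(out, "gate_report") <- list(thresholds = thr, n_positive = n_pos,
                                   n_input = nrow(cells), n_kept = sum(pos))
  out
}

#' Z-score biomarkers against the untreated control cohort
#'
#' Each biomarker column (and the cell DTA) is centered on the median and
#' scaled by the sample standard deviation of the control-cohort cells, so
#' all treated cohorts are expressed in control-anchored units.
#'
#' @param cells a QC-filtered cell table with a `cohort` column.
#' @param spec a [normalization_spec()]; `control_label` selects the
#'   control cells.
#' @param columns columns to z-score; default all marker columns plus `dta`.
#' @return The cell table with columns replaced by z-scores; attribute
#'   `"control_stats"` records the per-column median, SD and control count.
#' @export
zscore_to_control <- function(cells, spec = normalization_spec(),
                              columns = NULL) {
  if (is.null(columns)) {
    columns <- marker_cols(cells)
    if ("dta" %in% names(cells)) columns <- c(columns, "dta")
  }
  ctrl <- cells$cohort == spec$control_label
  if (!any(ctrl, na.rm = TRUE))
    stop("no cells with control cohort label `", spec$control_label, "`",
         call. = FALSE)
  out <- cells
  stats_df <- data.frame(column = columns, median = NA_real_, sd = NA_real_,
                         n_control = sum(ctrl, na.rm = TRUE))
  for (i in seq_along(columns)) {
    col <- columns[i]
    cv <- cells[[col]][which(ctrl)]
    cv <- cv[is.finite(cv)]
    m <- stats::median(cv)
    s <- stats::sd(cv)
    if (!is.finite(s) || s == 0)
      stop("control SD is zero for column `", col,
           "`; cannot z-score a constant column", call. = FALSE)
    out[[col]] <- (cells[[col]] - m) / s
    stats_df$median[i] <- m; stats_df$sd[i] <- s
  }
  out <- keep_attrs(out, cells)
  attr(out, "control_stats") <- stats_df
  out
}

#' Run the full QC / normalization chain
#'
#' Fixed order: exposure normalization, autofluorescence subtraction,
#' outlier filtering, epithelial gating, control-anchored z-scoring.
#'
#' @param cells a combined cell table (all tissues/cohorts).
#' @param spec a [normalization_spec()].
#' @param exposures,wavelength_map see [normalize_exposure()] and
#'   [subtract_autofluorescence()]; default to the table attributes.
#' @return The fully processed cell table; attribute `"qc_chain"` collects
#'   the stage reports.
#' @export
qc_normalize <- function(cells, spec = normalization_spec(),
                         exposures = NULL, wavelength_map = NULL) {
  x <- normalize_exposure(cells, exposures)
  x <- subtract_autofluorescence(x, wavelength_map)
  x <- filter_outliers(x, spec)
  qc_rep <- attr(x, "qc_report")
  x <- gate_epithelial(x, spec)
  gate_rep <- attr(x, "gate_report")
  x <- zscore_to_control(x, spec)
  attr(x, "qc_chain") <- list(outliers = qc_rep, gate = gate_rep,
                              control_stats = attr(x, "control_stats"))
  x
}
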