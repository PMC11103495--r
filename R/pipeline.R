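#' Process one tissue: register, mask, DTA, segment, quantify
#'
#' Runs the per-tissue stages on a multi-round stack (as produced by
#' [generate_phantom()] or [load_stack()]): every round is registered to the
#' first round on its DAPI channel and resampled onto the reference grid;
#' the tissue mask is built from the untargeted-probe channel; the DTA map
#' is computed from the paired probe channels; nuclei are segmented from the
#' reference DAPI; and per-cell features are extracted from the registered
#' marker/autofluorescence stack plus the DTA map.
#'
#' @param rounds named list of rounds (first = reference, containing `DAPI`,
#'   `T`, `UnT`); later rounds contain `DAPI` plus marker or `AF_*`
#'   channels.
#' @param sf a `scaling_factor` (or positive number).
#' @param cohort cohort label stamped on the cell table.
#' @param floor_eps denominator floor for the DTA ratio.
#' @param min_area_px,cell_expansion_px segmentation / feature parameters.
#' @param min_score registration confidence floor.
#' @return A list: `cells` (cell table), `dta` (`dta_map`), `mask`,
#'   `labels`, `transforms` (per non-reference round), `stack` (registered
#'   channels used for features).
#' @export
process_tissue <- function(rounds, sf, cohort = NA_character_,
                           floor_eps = 1e-6, min_area_px = 20,
                           cell_expansion_px = 3, min_score = 0.1) {
  if (length(rounds) == 0L) stop("no imaging rounds", call. = FALSE)
  ref_name <- names(rounds)[1]
  ref <- rounds[[ref_name]]
  for (need in c("DAPI", "T", "UnT"))
    if (!need %in% names(ref))
      stop("reference round must contain channel `", need, "`",
           call. = FALSE)

  transforms <- list()
  stack <- list()
  # reference-round AF channels are already on the reference grid
  for (mk in setdiff(names(ref), c("DAPI", "T", "UnT")))
    stack[[mk]] <- ref[[mk]]
  for (rn in names(rounds)[-1]) {
    tf <- register_rounds(ref$DAPI, rounds[[rn]]$DAPI, min_score = min_score)
    transforms[[rn]] <- tf
    for (mk in setdiff(names(rounds[[rn]]), "DAPI"))
      stack[[mk]] <- warp_channel(rounds[[rn]][[mk]], tf)
  }

  mask <- make_tissue_mask(ref$UnT)
  dta <- compute_dta_map(ref$T, ref$UnT, sf, mask, floor_eps = floor_eps)
  labels <- segment_nuclei(ref$DAPI, min_area_px = min_area_px)
  cells <- extract_features(labels, stack, dta,
                            cell_expansion_px = cell_expansion_px,
                            cohort = cohort)
  list(cells = cells, dta = dta, mask = mask, labels = labels,
       transforms = transforms, stack = stack)
}

#' Run the full study pipeline
#'
#' Executes calibrate, then per tissue register / DTA / segment / quantify,
#' then the cohort-level QC chain and statistics, in that order. Designed
#' around a study list so phantom-based and file-based tissues mix freely.
#'
#' @param study a list with elements:
#'   * `tissues`: list of tissues; each has `id`, `cohort`, and either
#'     `phantom` (a [phantom_config()]) or `manifest` (path for
#'     [load_stack()]).
#'   * `titration`: either a list of [generate_titration()] arguments, a
#'     titration series data frame, or a single positive number used as the
#'     scaling factor directly.
#'   * `spec`: a [normalization_spec()] (optional).
#'   * `seed`: base seed; tissue i's phantom uses `seed + i - 1` unless its
#'     config sets one explicitly.
#' @param out_dir optional output directory; when given, the run writes the
#'   cell tables, scaling factor, transforms, QC report, statistics and
#'   provenance (config hash, seed, package version, SF) as CSV/JSON, plus
#'   per-tissue DTA/mask/label TIFFs.
#' @return A list of class `tripodd_run`: `sf`, `cells_raw`, `cells`
#'   (QC'd, z-scored), `qc`, `stats`, `tissues` (per-tissue stage outputs),
#'   `provenance`.
#' @export
run_pipeline <- function(study, out_dir = NULL) {
  if (is.null(study$tissues) || length(study$tissues) == 0L)
    stop("pipeline stage `validate`: study has no tissues", call. = FALSE)
  spec <- study$spec %||% normalization_spec()
  seed <- study$seed %||% 1L

  # --- calibrate ---
  sf <- tryCatch({
    tit <- study$titration
    if (inherits(tit, "scaling_factor")) tit
    else if (is.numeric(tit) && length(tit) == 1L)
      structure(list(sf = tit, slope_T = NA_real_, slope_UnT = NA_real_),
                class = "scaling_factor")
    else if (is.data.frame(tit)) calibrate_sf(tit)
    else if (is.list(tit)) calibrate_sf(do.call(generate_titration, tit)$series)
    else stop("study$titration must be a number, series or argument list")
  }, error = function(e)
    stop("pipeline stage `calibrate`: ", conditionMessage(e), call. = FALSE))

  # --- per-tissue processing ---
  tissues <- list()
  tables <- list()
  for (i in seq_along(study$tissues)) {
    ts <- study$tissues[[i]]
    id <- ts$id %||% paste0("tissue", i)
    res <- tryCatch({
      rounds <- if (!is.null(ts$phantom)) {
        cfg <- ts$phantom
        if (is.null(ts$phantom_seeded) || !ts$phantom_seeded)
          cfg$seed <- as.integer(seed + i - 1L)
        generate_phantom(cfg)$rounds
      } else if (!is.null(ts$manifest)) {
        load_stack(ts$manifest)
      } else stop("tissue needs `phantom` or `manifest`")
      process_tissue(rounds, sf, cohort = ts$cohort %||% NA_character_)
    }, error = function(e)
      stop("pipeline stage `quantify` (tissue ", id, "): ",
           conditionMessage(e), call. = FALSE))
    res$cells$tissue <- id
    tissues[[id]] <- res
    tables[[id]] <- res$cells
  }

  cells_raw <- do.call(rbind, tables)
  rownames(cells_raw) <- NULL
  cells_raw$cell_uid <- paste0(cells_raw$tissue, "_", cells_raw$cell_id)
  cells_raw <- keep_attrs(cells_raw, tables[[1]])

  # --- qc / normalization ---
  cells <- tryCatch(qc_normalize(cells_raw, spec),
                    error = function(e)
                      stop("pipeline stage `qc`: ", conditionMessage(e),
                           call. = FALSE))

  # --- statistics ---
  stats_out <- tryCatch({
    out <- list()
    cohorts <- split(cells$dta[is.finite(cells$dta)],
                     cells$cohort[is.finite(cells$dta)])
    cohorts <- cohorts[lengths(cohorts) >= 2L]
    if (length(cohorts) >= 2L)
      out$anova_dta <- anova_lsd(cohorts, alpha = 0.05)
    if (all(c("EGFR", "dta") %in% names(cells))) {
      ok <- is.finite(cells$EGFR) & is.finite(cells$dta)
      if (sum(ok) >= 3L && stats::sd(cells$EGFR[ok]) > 0 &&
          stats::sd(cells$dta[ok]) > 0)
        out$pearson_egfr_dta <- pearson_cor(cells$EGFR[ok], cells$dta[ok])
    }
    out$cohort_dta <- lapply(split(cells$dta, cells$cohort),
                             function(v) unclass(cohort_summary(v)))
    out
  }, error = function(e)
    stop("pipeline stage `stats`: ", conditionMessage(e), call. = FALSE))

  prov <- list(config_hash = study_hash(study), seed = seed,
               sf_used = sf$sf,
               package_version = as.character(utils::packageVersion("tripodd")),
               timestamp = NA_character_)

  run <- structure(list(sf = sf, cells_raw = cells_raw, cells = cells,
                        qc = attr(cells, "qc_chain"), stats = stats_out,
                        tissues = tissues, provenance = prov),
                   class = "tripodd_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# stable content hash of the study config (serialized canonically)
study_hash <- function(study) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(study, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cell_table(run$cells_raw, file.path(out_dir, "cells_raw.csv"))
  write_cell_table(run$cells, file.path(out_dir, "cells.csv"))
  write_sf_json(run$sf, file.path(out_dir, "sf.json"))
  jsonlite::write_json(run$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  qc <- run$qc
  qc$outliers$flags <- NULL
  jsonlite::write_json(qc, file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(lapply(run$stats, unclass),
                       file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (id in names(run$tissues)) {
    ts <- run$tissues[[id]]
    write_dta_tiff(ts$dta, file.path(out_dir, paste0("dta_", id, ".tif")))
    write_mask_tiff(ts$mask, file.path(out_dir, paste0("mask_", id, ".tif")))
    write_labels_tiff(ts$labels,
                      file.path(out_dir, paste0("labels_", id, ".tif")))
    if (length(ts$transforms))
      jsonlite::write_json(lapply(ts$transforms, unclass),
                           file.path(out_dir,
                                     paste0("transforms_", id, ".json")),
                           auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' @export
print.tripodd_run <- function(x, ...) {
  cat(sprintf("<tripodd_run> SF %.4f; %d tissues; %d cells raw -> %d after QC\n",
              x$sf$sf, length(x$tissues), nrow(x$cells_raw), nrow(x$cells)))
  invisible(x)
}
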