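# Shared fixtures: small phantoms and hand-built cell tables.

small_phantom_config <- function(n_cells = 40, field = 256, seed = 3, ...) {
  phantom_config(n_cells = n_cells, field_size = c(field, field),
                 seed = seed, ...)
}

clean_phantom_config <- function(n_cells = 40, field = 256, seed = 3, ...) {
  # noiseless, autofluorescence-free: the exact-oracle regime
  phantom_config(n_cells = n_cells, field_size = c(field, field), seed = seed,
                 autofluorescence = c(Cy2 = 0, Cy3 = 0, Cy5 = 0, Cy7 = 0),
                 noise_sigma = 0, ...)
}

# match segmented cells to truth rows by nearest centroid
match_to_truth <- function(cells, truth) {
  vapply(seq_len(nrow(cells)), function(i) {
    which.min((truth$centroid_row - cells$centroid_row[i])^2 +
              (truth$centroid_col - cells$centroid_col[i])^2)
  }, 0L)
}

# build a cell table by hand with the attributes extract_features stamps
make_cell_table <- function(df, intensity_cols = NULL, wavelengths = NULL,
                            exposures = NULL) {
  if (is.null(intensity_cols))
    intensity_cols <- setdiff(names(df),
                              c("cell_id", "centroid_row", "centroid_col",
                                "nuclear_size", "dta", "dta_valid_frac",
                                "cohort", "tissue", "cell_uid"))
  attr(df, "intensity_cols") <- intensity_cols
  attr(df, "wavelengths") <- wavelengths
  attr(df, "exposures") <- exposures
  class(df) <- c("cell_table", "data.frame")
  df
}
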