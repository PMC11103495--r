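#' Fit a linear calibration trend line to a titration series
#'
#' Ordinary least-squares fit of mean fluorescence intensity against probe
#' concentration. The intercept is fitted, not forced through zero; the
#' scaling factor downstream uses slopes only.
#'
#' @param series data frame with columns `concentration` and
#'   `mean_intensity` (one probe), or the `series` element of
#'   [generate_titration()] filtered to one probe.
#' @return A list of class `titration_fit`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_titration <- function(series) {
  if (!all(c("concentration", "mean_intensity") %in% names(series)))
    stop("series needs columns `concentration` and `mean_intensity`",
         call. = FALSE)
  x <- series$concentration; y <- series$mean_intensity
  if (length(unique(x)) < 2L)
    stop("need at least 2 distinct concentrations to fit a trend line",
         call. = FALSE)
  if (any(y < 0)) stop("intensities must be nonnegative", call. = FALSE)
  fit <- stats::lm(y ~ x)
  res <- sum(stats::residuals(fit)^2)
  tot <- sum((y - mean(y))^2)
  # a flat series has zero total variance; a perfect flat fit counts as r2 = 1
  r2 <- if (tot < .Machine$double.eps) (if (res < 1e-12) 1 else 0) else 1 - res / tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(x)),
            class = "titration_fit")
}

#' Compute the scaling factor from the two titration fits
#'
#' The scaling factor equalizes the fluorescence-per-concentration response
#' of the two probes: it is the ratio of the untargeted trend-line slope to
#' the targeted trend-line slope, so that `sf * I_T` and `I_UnT` are on the
#' same concentration-equivalent scale.
#'
#' @param fit_T,fit_UnT [fit_titration()] results for the targeted and
#'   untargeted probes.
#' @return A list of class `scaling_factor`: `sf`, both slopes, intercepts
#'   and per-fit r-squared values.
#' @export
compute_scaling_factor <- function(fit_T, fit_UnT) {
  if (fit_T$slope <= 0 || fit_UnT$slope <= 0)
    stop("calibration failed: non-positive titration slope", call. = FALSE)
  structure(list(sf = fit_UnT$slope / fit_T$slope,
                 slope_T = fit_T$slope, slope_UnT = fit_UnT$slope,
                 intercept_T = fit_T$intercept, intercept_UnT = fit_UnT$intercept,
                 r_squared_T = fit_T$r_squared, r_squared_UnT = fit_UnT$r_squared),
            class = "scaling_factor")
}

#' Calibrate the scaling factor from a combined titration table
#'
#' Convenience wrapper: splits a `(probe, concentration, mean_intensity)`
#' table into the targeted and untargeted series, fits each trend line and
#' returns the scaling factor.
#'
#' @param series data frame with columns `probe` (values `"targeted"` /
#'   `"untargeted"`), `concentration`, `mean_intensity`.
#' @return A `scaling_factor`.
#' @export
calibrate_sf <- function(series) {
  if (!"probe" %in% names(series))
    stop("series needs a `probe` column", call. = FALSE)
  fit_t <- fit_titration(series[series$probe == "targeted", ])
  fit_u <- fit_titration(series[series$probe == "untargeted", ])
  compute_scaling_factor(fit_t, fit_u)
}

#' @export
print.scaling_factor <- function(x, ...) {
  cat(sprintf("<scaling_factor> SF = %.4f (slope_UnT %.4f / slope_T %.4f; r2 %.3f / %.3f)\n",
              x$sf, x$slope_UnT, x$slope_T, x$r_squared_UnT, x$r_squared_T))
  invisible(x)
}

#' Read / write a titration series as CSV
#'
#' Columns: `probe`, `concentration`, `mean_intensity`.
#' @param path file path.
#' @return `read_titration_csv` returns the data frame.
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe", "concentration", "mean_intensity")
  if (!all(need %in% names(df)))
    stop("titration CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_titration_csv
#' @param series titration data frame.
#' @export
write_titration_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a scaling factor as JSON
#' @param path file path.
#' @return `read_sf_json` returns a `scaling_factor`.
#' @export
read_sf_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "scaling_factor")
}

#' @rdname read_sf_json
#' @param sf a `scaling_factor`.
#' @export
write_sf_json <- function(sf, path) {
  jsonlite::write_json(unclass(sf), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
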