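#' Configuration for the synthetic tissue phantom
#'
#' Builds the parameter set for [generate_phantom()]. The phantom emulates a
#' xenograft tissue section imaged with paired targeted/untargeted probes and
#' several cyclic-immunofluorescence rounds: densely packed, similarly sized
#' nuclei; per-cell receptor density and nonspecific probe accumulation (both
#' log-normal); partial occupancy of the target by an unlabeled parent drug;
#' per-wavelength autofluorescence; additive noise; and a rigid shift per
#' imaging round.
#'
#' The forward model inside a cell footprint is
#' \deqn{I_T = s_T (B (1-f) R + N), \qquad I_{UnT} = s_{UnT} N}
#' with receptor density \eqn{R}, nonspecific accumulation \eqn{N}, binding
#' gain \eqn{B}, drug occupancy \eqn{f} and channel gains \eqn{s_T, s_{UnT}};
#' outside cells but inside the tissue both probes see only the background
#' uptake level. The true per-cell drug target availability is therefore
#' \eqn{B (1-f) R / N}, and the true scaling factor is
#' \eqn{s_{UnT}/s_T}.
#'
#' @param n_cells number of cells to place.
#' @param field_size image size in pixels, `c(rows, cols)`.
#' @param nucleus_radius_px mean and SD of the nuclear radius in pixels.
#' @param annulus_px cytoplasm width (px) around each nucleus; the cell
#'   footprint is the nucleus disk plus this annulus.
#' @param receptor_density log-normal parameters (`meanlog`, `sdlog`) of the
#'   per-cell receptor density R.
#' @param occupancy_f fraction in \[0, 1\] of target sites occupied by the
#'   unlabeled parent drug.
#' @param nonspecific log-normal parameters of the per-cell nonspecific
#'   accumulation N.
#' @param binding_gain binding gain B converting available receptor to bound
#'   targeted probe.
#' @param slope_T,slope_UnT fluorescence-per-concentration gains of the
#'   targeted and untargeted channels.
#' @param autofluorescence named per-wavelength mean autofluorescence levels.
#' @param tissue_background nonspecific probe accumulation (concentration
#'   units) in tissue outside cell footprints.
#' @param noise_sigma additive Gaussian noise SD (truncated at zero).
#' @param noise_model `"gaussian"` or `"poisson"` (Poisson shot noise on the
#'   expected signal, then Gaussian read noise).
#' @param frac_stromal fraction of cells that are stromal (low epithelial
#'   marker expression, reduced receptor density).
#' @param stromal_receptor_frac receptor-density multiplier for stromal cells.
#' @param round_shifts named list of per-round rigid shifts `c(dy, dx)` in
#'   pixels; names must match the round names (`"ipai"`, `"af"`, and the
#'   rounds referenced by `marker_spec`). The first round is the reference
#'   and conventionally has shift `c(0, 0)`.
#' @param exposure_ms named per-wavelength exposure times in ms.
#' @param dapi_level mean nuclear DAPI intensity.
#' @param marker_spec data frame describing cyCIF markers: columns `marker`,
#'   `wavelength`, `round`, `kind` (`"lognormal"`, `"epithelial"`,
#'   `"bimodal"`, `"receptor"`), `meanlog`, `sdlog`, and for
#'   `kind = "receptor"` a `scale` column (expression = scale * R * noise).
#' @param seed integer seed; the whole phantom is reproducible bit-for-bit.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(n_cells = 200,
                           field_size = c(640, 640),
                           nucleus_radius_px = c(mean = 6, sd = 1),
                           annulus_px = 4,
                           receptor_density = list(meanlog = log(50), sdlog = 0.35),
                           occupancy_f = 0,
                           nonspecific = list(meanlog = log(50), sdlog = 0.30),
                           binding_gain = 1,
                           slope_T = 3,
                           slope_UnT = 6,
                           autofluorescence = c(Cy2 = 2, Cy3 = 2, Cy5 = 2, Cy7 = 2),
                           tissue_background = 5,
                           noise_sigma = 2,
                           noise_model = c("gaussian", "poisson"),
                           frac_stromal = 0.1,
                           stromal_receptor_frac = 0.2,
                           round_shifts = list(ipai = c(0, 0), af = c(3, -2),
                                               r2 = c(5, 4), r3 = c(-6, 3)),
                           exposure_ms = c(DAPI = 10, Cy2 = 50, Cy3 = 50,
                                           Cy5 = 100, Cy7 = 100),
                           dapi_level = 100,
                           marker_spec = default_marker_spec(),
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (length(occupancy_f) != 1L || occupancy_f < 0 || occupancy_f > 1)
    stop("`occupancy_f` must be a single value in [0, 1]", call. = FALSE)
  if (slope_T <= 0 || slope_UnT <= 0)
    stop("channel gains `slope_T` and `slope_UnT` must be positive", call. = FALSE)
  if (any(exposure_ms <= 0)) stop("exposures must be positive", call. = FALSE)
  if (nucleus_radius_px[[1]] <= 0)
    stop("nuclear radius must be positive", call. = FALSE)
  if (n_cells < 0) stop("`n_cells` must be nonnegative", call. = FALSE)
  if (!all(c("meanlog", "sdlog") %in% names(receptor_density)) ||
      !all(c("meanlog", "sdlog") %in% names(nonspecific)) ||
      receptor_density$sdlog < 0 || nonspecific$sdlog < 0)
    stop("distribution specs need nonnegative `meanlog`/`sdlog` entries",
         call. = FALSE)
  for (s in round_shifts)
    if (any(abs(s) >= field_size))
      stop("round shift larger than the field", call. = FALSE)
  cfg <- list(n_cells = as.integer(n_cells), field_size = as.integer(field_size),
              nucleus_radius_px = nucleus_radius_px, annulus_px = annulus_px,
              receptor_density = receptor_density, occupancy_f = occupancy_f,
              nonspecific = nonspecific, binding_gain = binding_gain,
              slope_T = slope_T, slope_UnT = slope_UnT,
              autofluorescence = autofluorescence,
              tissue_background = tissue_background,
              noise_sigma = noise_sigma, noise_model = noise_model,
              frac_stromal = frac_stromal,
              stromal_receptor_frac = stromal_receptor_frac,
              round_shifts = round_shifts, exposure_ms = exposure_ms,
              dapi_level = dapi_level, marker_spec = marker_spec,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

#' Default cyCIF marker panel for the phantom
#'
#' Two marker rounds: CK8/E-Cad/EGFR and Ki67/pEGFR/CC3. CK8 and E-Cad are
#' epithelial (high in tumor cells, low in stroma); EGFR and pEGFR scale with
#' the cell's receptor density; CC3 is bimodal (a small punctate-positive
#' apoptotic subset, near zero elsewhere).
#'
#' @return A data frame with one row per marker.
#' @export
default_marker_spec <- function() {
  data.frame(
    marker = c("CK8", "E-Cad", "EGFR", "Ki67", "pEGFR", "CC3"),
    wavelength = c("Cy3", "Cy5", "Cy7", "Cy3", "Cy5", "Cy7"),
    round = c("r2", "r2", "r2", "r3", "r3", "r3"),
    kind = c("epithelial", "epithelial", "receptor", "lognormal",
             "receptor", "bimodal"),
    meanlog = c(log(40), log(40), NA, log(20), NA, log(40)),
    sdlog = c(0.3, 0.3, 0.15, 0.5, 0.15, 0.3),
    scale = c(NA, NA, 0.6, NA, 0.4, NA),
    stringsAsFactors = FALSE
  )
}

# Place n non-overlapping cell centers inside an ellipse by rejection
# sampling; min separation keeps whole footprints (nucleus + annulus) apart.
place_cells <- function(n, field, radii, annulus) {
  if (n == 0L) return(cbind(row = numeric(0), col = numeric(0)))
  cy <- (field[1] - 1) / 2; cx <- (field[2] - 1) / 2
  a <- 0.45 * field[1]; b <- 0.45 * field[2]
  rows <- numeric(n); cols <- numeric(n)
  foot <- radii + annulus
  placed <- 0L; tries <- 0L; max_tries <- 2000L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place all nuclei without overlap; ",
           "reduce `n_cells` or enlarge `field_size`", call. = FALSE)
    u <- sqrt(runif(1)); ang <- runif(1, 0, 2 * pi)
    r <- cy + u * (a - foot[placed + 1L] - 1) * sin(ang)
    c <- cx + u * (b - foot[placed + 1L] - 1) * cos(ang)
    if (placed > 0L) {
      d2 <- (rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2
      mind <- foot[seq_len(placed)] + foot[placed + 1L] + 2
      if (any(d2 < mind^2)) next
    }
    placed <- placed + 1L
    rows[placed] <- r; cols[placed] <- c
  }
  cbind(row = rows, col = cols)
}

# Paint per-cell values onto disks. Returns a matrix; `values` is one value
# per cell, `radii` the disk radius per cell. Coordinates are 0-based,
# pixel-centered.
paint_disks <- function(field, centers, radii, values) {
  img <- matrix(0, field[1], field[2])
  if (nrow(centers) == 0L) return(img)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]; rad <- radii[k]
    ri <- max(1L, floor(r0 - rad) + 1L):min(field[1], ceiling(r0 + rad) + 1L)
    ci <- max(1L, floor(c0 - rad) + 1L):min(field[2], ceiling(c0 + rad) + 1L)
    sub <- outer((ri - 1) - r0, (ci - 1) - c0,
                 function(dy, dx) dy * dy + dx * dx) <= rad * rad
    img[ri, ci][sub] <- values[k]
  }
  img
}

ellipse_mask <- function(field) {
  cy <- (field[1] - 1) / 2; cx <- (field[2] - 1) / 2
  a <- 0.45 * field[1]; b <- 0.45 * field[2]
  outer(((seq_len(field[1]) - 1) - cy) / a,
        ((seq_len(field[2]) - 1) - cx) / b,
        function(y, x) y * y + x * x) <= 1
}

add_noise <- function(img, sigma, model) {
  if (model == "poisson") img <- matrix(rpois(length(img), img), nrow(img))
  if (sigma > 0) img <- img + matrix(rnorm(length(img), 0, sigma), nrow(img))
  pmax(img, 0)
}

draw_marker_expression <- function(spec_row, n, epithelial, receptor) {
  kind <- spec_row$kind
  if (kind == "lognormal") {
    rlnorm(n, spec_row$meanlog, spec_row$sdlog)
  } else if (kind == "epithelial") {
    e <- rlnorm(n, spec_row$meanlog, spec_row$sdlog)
    lo <- rlnorm(n, log(2), spec_row$sdlog)
    ifelse(epithelial, e, lo)
  } else if (kind == "receptor") {
    spec_row$scale * receptor * rlnorm(n, 0, spec_row$sdlog)
  } else if (kind == "bimodal") {
    pos <- runif(n) < 0.1
    ifelse(pos, rlnorm(n, spec_row$meanlog, spec_row$sdlog),
           rlnorm(n, log(1), spec_row$sdlog))
  } else stop("unknown marker kind: ", kind, call. = FALSE)
}

#' Generate a synthetic multi-round tissue phantom with known ground truth
#'
#' Produces an image stack per imaging round (the paired-agent round, an
#' autofluorescence round, and the cyCIF marker rounds of the config's
#' `marker_spec`), plus a per-cell truth table. Every round is the base scene
#' rigidly displaced by that round's true shift, then corrupted with fresh
#' noise, so registration, segmentation, feature extraction, QC and the DTA
#' equation can all be validated against known values.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `rounds` (named list of rounds, each a named
#'   list of [channel_image()]s including `"DAPI"`), `truth` (data frame:
#'   one row per cell with centroid, nuclear area, receptor density,
#'   nonspecific accumulation, marker expressions, epithelial status, and
#'   `true_dta`), `sf_true`, `round_shifts` and `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  field <- config$field_size
  n <- config$n_cells

  radii <- pmax(2, rnorm(n, config$nucleus_radius_px[[1]],
                         config$nucleus_radius_px[[2]]))
  centers <- place_cells(n, field, radii, config$annulus_px)
  epithelial <- runif(n) >= config$frac_stromal
  receptor <- rlnorm(n, config$receptor_density$meanlog,
                     config$receptor_density$sdlog)
  receptor[!epithelial] <- receptor[!epithelial] * config$stromal_receptor_frac
  nonspec <- rlnorm(n, config$nonspecific$meanlog, config$nonspecific$sdlog)
  af_mult <- rlnorm(n, 0, 0.25)
  dapi_mult <- rlnorm(n, 0, 0.1)

  f <- config$occupancy_f; B <- config$binding_gain
  true_dta <- if (n > 0) B * (1 - f) * receptor / nonspec else numeric(0)

  markers <- config$marker_spec
  expr <- lapply(seq_len(nrow(markers)), function(i)
    draw_marker_expression(markers[i, ], n, epithelial, receptor))
  names(expr) <- markers$marker

  foot <- radii + config$annulus_px
  tissue <- ellipse_mask(field)

  # base (unshifted) scenes
  nuc_scene <- paint_disks(field, centers, radii, config$dapi_level * dapi_mult)
  nuclear_area <- if (n > 0) {
    lbl <- paint_disks(field, centers, radii, seq_len(n))
    tabulate(lbl[lbl > 0], nbins = n)
  } else integer(0)

  cell_scene <- function(values, background = 0) {
    img <- matrix(0, field[1], field[2])
    img[tissue] <- background
    fp <- paint_disks(field, centers, foot, values)
    img[fp > 0] <- fp[fp > 0]
    img
  }
  targeted_scene <- cell_scene(
    config$slope_T * (B * (1 - f) * receptor + nonspec),
    background = config$slope_T * config$tissue_background)
  untargeted_scene <- cell_scene(
    config$slope_UnT * nonspec,
    background = config$slope_UnT * config$tissue_background)
  af_scene <- lapply(config$autofluorescence, function(level) {
    if (level == 0) return(matrix(0, field[1], field[2]))
    cell_scene(level * af_mult, background = level)
  })
  marker_scene <- lapply(expr, cell_scene)

  wl_exp <- function(wl) unname(config$exposure_ms[[wl]])
  rounds <- list()
  round_names <- names(config$round_shifts)
  for (rn in round_names) {
    s <- config$round_shifts[[rn]]
    sh <- function(img) shift_scene(img, s[1], s[2])
    chans <- list(DAPI = channel_image(
      add_noise(sh(nuc_scene), config$noise_sigma, config$noise_model),
      "DAPI", "DAPI", wl_exp("DAPI")))
    if (rn == "ipai") {
      for (wl in c("Cy2", "Cy3")) {
        chans[[paste0("AF_", wl)]] <- channel_image(
          add_noise(sh(af_scene[[wl]]), config$noise_sigma, config$noise_model),
          wl, paste0("AF_", wl), wl_exp(wl))
      }
      chans[["T"]] <- channel_image(
        add_noise(sh(targeted_scene + af_scene[["Cy5"]]),
                  config$noise_sigma, config$noise_model),
        "Cy5", "T", wl_exp("Cy5"))
      chans[["UnT"]] <- channel_image(
        add_noise(sh(untargeted_scene + af_scene[["Cy7"]]),
                  config$noise_sigma, config$noise_model),
        "Cy7", "UnT", wl_exp("Cy7"))
    } else if (rn == "af") {
      for (wl in names(af_scene)) {
        chans[[paste0("AF_", wl)]] <- channel_image(
          add_noise(sh(af_scene[[wl]]), config$noise_sigma, config$noise_model),
          wl, paste0("AF_", wl), wl_exp(wl))
      }
    } else {
      rows <- which(markers$round == rn)
      for (i in rows) {
        m <- markers$marker[i]; wl <- markers$wavelength[i]
        chans[[m]] <- channel_image(
          add_noise(sh(marker_scene[[m]] + af_scene[[wl]]),
                    config$noise_sigma, config$noise_model),
          wl, m, wl_exp(wl))
      }
    }
    rounds[[rn]] <- chans
  }

  truth <- data.frame(cell_id = seq_len(n),
                      centroid_row = centers[, 1], centroid_col = centers[, 2],
                      radius_px = radii, nuclear_area_px = nuclear_area,
                      epithelial = epithelial, receptor = receptor,
                      nonspecific = nonspec, af_mult = af_mult,
                      true_dta = true_dta)
  for (m in names(expr)) truth[[m]] <- expr[[m]]

  list(rounds = rounds, truth = truth,
       sf_true = config$slope_UnT / config$slope_T,
       round_shifts = config$round_shifts, config = config)
}

# Displace a scene by (dy, dx): the output at (y, x) shows the scene at
# (y - dy, x - dx). Integer shifts are exact; fractional use bilinear.
shift_scene <- function(img, dy, dx) {
  if (dy == 0 && dx == 0) return(img)
  if (dy == round(dy) && dx == round(dx)) {
    out <- matrix(0, nrow(img), ncol(img))
    src_r <- seq_len(nrow(img)) - dy
    src_c <- seq_len(ncol(img)) - dx
    ok_r <- src_r >= 1 & src_r <= nrow(img)
    ok_c <- src_c >= 1 & src_c <= ncol(img)
    out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
    out
  } else {
    warp_rigid(img, dy = -dy, dx = -dx, theta = 0)$pixels
  }
}

#' Generate a titration image series for scaling-factor calibration
#'
#' Simulates imaging each probe at a set of titrated concentrations: every
#' image is uniform at `slope * concentration + intercept` plus optional
#' Gaussian noise, mirroring how a linear calibration trend line per probe is
#' produced in practice.
#'
#' @param slope_T,slope_UnT fluorescence-per-concentration gains (> 0).
#' @param concentrations numeric vector (>= 2 distinct, all >= 0).
#' @param noise_sigma additive Gaussian noise SD.
#' @param seed integer seed.
#' @param img_size image size in pixels.
#' @param intercept_T,intercept_UnT baseline intensities.
#' @return A list with `images` (per probe, one matrix per concentration) and
#'   `series`, a data frame of `(probe, concentration, mean_intensity)` ready
#'   for [fit_titration()].
#' @export
generate_titration <- function(slope_T, slope_UnT, concentrations,
                               noise_sigma = 0, seed = 1L,
                               img_size = c(64, 64),
                               intercept_T = 0, intercept_UnT = 0) {
  if (slope_T <= 0 || slope_UnT <= 0)
    stop("slopes must be positive", call. = FALSE)
  if (length(unique(concentrations)) < 2L)
    stop("need at least 2 distinct concentrations", call. = FALSE)
  if (any(concentrations < 0))
    stop("concentrations must be nonnegative", call. = FALSE)
  set.seed(seed)
  make <- function(slope, intercept) lapply(concentrations, function(conc) {
    img <- matrix(slope * conc + intercept, img_size[1], img_size[2])
    if (noise_sigma > 0)
      img <- pmax(img + matrix(rnorm(length(img), 0, noise_sigma),
                               img_size[1]), 0)
    img
  })
  images <- list(targeted = make(slope_T, intercept_T),
                 untargeted = make(slope_UnT, intercept_UnT))
  series <- data.frame(
    probe = rep(c("targeted", "untargeted"), each = length(concentrations)),
    concentration = rep(concentrations, 2),
    mean_intensity = c(vapply(images$targeted, mean, 0),
                       vapply(images$untargeted, mean, 0)))
  list(images = images, series = series)
}
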