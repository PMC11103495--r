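test_that("well-separated phantom nuclei are segmented one-to-one", {
  cfg <- small_phantom_config(n_cells = 50, field = 256, seed = 3)
  ph <- generate_phantom(cfg)
  lab <- segment_nuclei(ph$rounds$ipai$DAPI)
  expect_equal(lab$n_cells, 50L)
  cells <- extract_features(lab, list())
  idx <- match_to_truth(cells, ph$truth)
  expect_equal(length(unique(idx)), 50L)
  expect_lt(max(abs(cells$centroid_row - ph$truth$centroid_row[idx])), 1)
  expect_lt(max(abs(cells$centroid_col - ph$truth$centroid_col[idx])), 1)
})

test_that("segmentation on phantoms reaches F1 >= 0.95 at default settings", {
  cfg <- small_phantom_config(n_cells = 60, field = 320, seed = 27)
  ph <- generate_phantom(cfg)
  lab <- segment_nuclei(ph$rounds$ipai$DAPI)
  cells <- extract_features(lab, list())
  d2 <- outer(cells$centroid_row, ph$truth$centroid_row, "-")^2 +
    outer(cells$centroid_col, ph$truth$centroid_col, "-")^2
  tp <- sum(apply(d2, 2, min) < 4)  # truth nuclei hit within 2 px
  prec <- tp / nrow(cells); rec <- tp / nrow(ph$truth)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gte(f1, 0.95)
})

test_that("a blank image yields zero cells with a warning", {
  expect_warning(lab <- segment_nuclei(matrix(0, 32, 32)), "blank")
  expect_equal(lab$n_cells, 0L)
  cells <- suppressWarnings(extract_features(lab, list()))
  expect_equal(nrow(cells), 0L)
})

test_that("two disks touching at one boundary are split by the watershed", {
  n <- 64
  img <- matrix(0, n, n)
  d2a <- outer((0:(n - 1)) - 30, (0:(n - 1)) - 22, function(a, b) a^2 + b^2)
  d2b <- outer((0:(n - 1)) - 30, (0:(n - 1)) - 37, function(a, b) a^2 + b^2)
  img[d2a <= 64 | d2b <= 64] <- 100
  lab <- segment_nuclei(img)
  expect_equal(lab$n_cells, 2L)
  cells <- extract_features(lab, list())
  expect_equal(sort(round(cells$centroid_col)), c(22, 37), tolerance = 1)
})

test_that("per-label areas conserve the foreground pixel count", {
  cfg <- small_phantom_config(n_cells = 30, field = 224, seed = 13)
  ph <- generate_phantom(cfg)
  lab <- segment_nuclei(ph$rounds$ipai$DAPI)
  cells <- extract_features(lab, list())
  expect_equal(sum(cells$nuclear_size), sum(lab$labels > 0))
})

test_that("feature means are exact on constant regions", {
  lab_img <- matrix(0L, 20, 20)
  lab_img[5:9, 5:9] <- 1L
  lab <- structure(list(labels = lab_img, n_cells = 1L),
                   class = "label_image")
  chan <- channel_image(matrix(4.25, 20, 20), "Cy3", "M1", 10)
  cells <- extract_features(lab, list(M1 = chan), cell_expansion_px = 2)
  expect_equal(cells$M1, 4.25)
  expect_equal(cells$nuclear_size, 25)
  expect_equal(attr(cells, "exposures")[["M1"]], 10)
})

test_that("phantom marker means recover truth within noise tolerance", {
  cfg <- small_phantom_config(n_cells = 40, field = 256, seed = 17,
                              noise_sigma = 1,
                              autofluorescence = c(Cy2 = 0, Cy3 = 0,
                                                   Cy5 = 0, Cy7 = 0),
                              round_shifts = list(ipai = c(0, 0),
                                                  r2 = c(0, 0),
                                                  r3 = c(0, 0)))
  ph <- generate_phantom(cfg)
  lab <- segment_nuclei(ph$rounds$ipai$DAPI)
  stack <- c(ph$rounds$r2, ph$rounds$r3)
  stack <- stack[!names(stack) %in% "DAPI"]
  cells <- extract_features(lab, stack)
  idx <- match_to_truth(cells, ph$truth)
  for (m in c("CK8", "EGFR", "Ki67")) {
    rel <- abs(cells[[m]] - ph$truth[[m]][idx]) /
      pmax(ph$truth[[m]][idx], 1)
    expect_lt(stats::median(rel), 0.05)
  }
})

test_that("cells with no valid DTA pixels are recorded as missing", {
  lab_img <- matrix(0L, 12, 12)
  lab_img[3:5, 3:5] <- 1L
  lab <- structure(list(labels = lab_img, n_cells = 1L),
                   class = "label_image")
  map <- compute_dta_map(matrix(1, 12, 12), matrix(0, 12, 12), 1,
                         floor_eps = 1e-6)
  cells <- extract_features(lab, list(), map, cell_expansion_px = 1)
  expect_true(is.na(cells$dta))
  expect_equal(cells$dta_valid_frac, 0)
})

test_that("feature extraction rejects mismatched shapes", {
  lab <- structure(list(labels = matrix(0L, 10, 10), n_cells = 0L),
                   class = "label_image")
  bad <- channel_image(matrix(1, 5, 5), "Cy3", "M")
  expect_error(extract_features(lab, list(M = bad)), "shape")
})
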