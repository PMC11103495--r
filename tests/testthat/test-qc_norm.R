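make_qc_table <- function(n = 100, seed = 1) {
  set.seed(seed)
  df <- data.frame(cell_id = seq_len(n),
                   nuclear_size = seq_len(n),
                   CK8 = rlnorm(n, log(40), 0.3),
                   `E-Cad` = rlnorm(n, log(40), 0.3),
                   EGFR = rlnorm(n, log(30), 0.4),
                   AF_Cy3 = rlnorm(n, log(2), 0.3),
                   AF_Cy5 = rlnorm(n, log(2), 0.3),
                   AF_Cy7 = rlnorm(n, log(2), 0.3),
                   dta = rlnorm(n, 0, 0.4),
                   cohort = rep(c("control", "treated"), length.out = n),
                   check.names = FALSE)
  make_cell_table(df,
                  intensity_cols = c("CK8", "E-Cad", "EGFR", "AF_Cy3",
                                     "AF_Cy5", "AF_Cy7"),
                  wavelengths = c(CK8 = "Cy3", `E-Cad` = "Cy5",
                                  EGFR = "Cy7"),
                  exposures = c(CK8 = 50, `E-Cad` = 100, EGFR = 100,
                                AF_Cy3 = 50, AF_Cy5 = 100, AF_Cy7 = 100))
}

test_that("exposure normalization divides intensities by exposure time", {
  tab <- make_cell_table(
    data.frame(cell_id = 1:2, nuclear_size = c(40, 50),
               M1 = c(500, 100), AF_Cy3 = c(250, 50), cohort = "control"),
    intensity_cols = c("M1", "AF_Cy3"),
    wavelengths = c(M1 = "Cy3"),
    exposures = c(M1 = 250, AF_Cy3 = 250))
  out <- normalize_exposure(tab)
  expect_equal(out$M1, c(2, 0.4))
  expect_equal(out$AF_Cy3, c(1, 0.2))
  # exposure of 1 ms leaves the table unchanged
  one <- normalize_exposure(tab, c(M1 = 1, AF_Cy3 = 1))
  expect_equal(one$M1, tab$M1)
  expect_error(normalize_exposure(tab, c(M1 = 0, AF_Cy3 = 1)), "positive")
  expect_error(normalize_exposure(tab, c(M1 = 10)), "no exposure")
})

test_that("autofluorescence is subtracted per cell and wavelength, unclipped", {
  tab <- make_cell_table(
    data.frame(cell_id = 1:3, nuclear_size = 40,
               M1 = c(10, 2, 5), AF_Cy3 = c(3, 3, 0), cohort = "control"),
    intensity_cols = c("M1", "AF_Cy3"),
    wavelengths = c(M1 = "Cy3"),
    exposures = c(M1 = 1, AF_Cy3 = 1))
  out <- subtract_autofluorescence(tab)
  expect_equal(out$M1, c(7, -1, 5))   # negatives retained, zero AF no-op
  bad <- tab
  attr(bad, "wavelengths") <- c(M1 = "Cy9")
  expect_error(subtract_autofluorescence(bad), "AF_Cy9")
  attr(bad, "wavelengths") <- NULL
  expect_error(subtract_autofluorescence(bad), "wavelength")
})

test_that("quantile outlier filter matches the brute-force oracle exactly", {
  n <- 100
  set.seed(5)
  af <- sample(seq_len(n))  # known AF ordering
  tab <- make_cell_table(
    data.frame(cell_id = seq_len(n), nuclear_size = seq_len(n),
               AF_Cy3 = af, cohort = "control"),
    intensity_cols = "AF_Cy3", wavelengths = NULL,
    exposures = c(AF_Cy3 = 1))
  out <- filter_outliers(tab, normalization_spec())
  # linear-interpolation quantiles of 1..100: q05 = 5.95, q95 = 95.05
  expect_equal(unname(quantile(1:100, 0.05, type = 7)), 5.95)
  oracle_keep <- which(tab$nuclear_size >= 5.95 & tab$nuclear_size <= 95.05 &
                       tab$AF_Cy3 <= quantile(af, 0.95, type = 7))
  expect_identical(out$cell_id, tab$cell_id[oracle_keep])
  rep <- attr(out, "qc_report")
  expect_equal(rep$n_removed_size, 10L)
  # sort-based oracle for the AF rule alone: exactly the top 5% flagged
  expect_identical(sort(rep$flags$cell_id[rep$flags$af_outlier]),
                   sort(tab$cell_id[order(-af)][1:5]))
})

test_that("a constant AF column removes no cells", {
  tab <- make_cell_table(
    data.frame(cell_id = 1:50, nuclear_size = 26:75, AF_Cy3 = 3,
               cohort = "control"),
    intensity_cols = "AF_Cy3", wavelengths = NULL, exposures = c(AF_Cy3 = 1))
  out <- filter_outliers(tab, normalization_spec())
  expect_equal(attr(out, "qc_report")$n_removed_af, 0L)
})

test_that("re-filtering at the same thresholds removes nothing", {
  tab <- make_qc_table(200, seed = 9)
  spec <- normalization_spec()
  once <- filter_outliers(tab, spec)
  rep1 <- attr(once, "qc_report")
  again <- once
  keep2 <- again$AF_Cy3 <= rep1$af_threshold &
    again$nuclear_size >= rep1$size_low & again$nuclear_size <= rep1$size_high
  expect_true(all(keep2))
  expect_error(filter_outliers(once[0, ], spec), "empty")
})

test_that("epithelial gating separates well-split populations", {
  set.seed(3)
  n <- 300
  epi <- rep(c(TRUE, FALSE), c(250, 50))
  mk <- function() ifelse(epi, rnorm(n, 100, 3), rnorm(n, 10, 3))
  tab <- make_cell_table(
    data.frame(cell_id = seq_len(n), nuclear_size = 40,
               CK8 = mk(), `E-Cad` = mk(), cohort = "control",
               check.names = FALSE),
    intensity_cols = c("CK8", "E-Cad"), wavelengths = NULL,
    exposures = c(CK8 = 1, `E-Cad` = 1))
  out <- gate_epithelial(tab, normalization_spec())
  expect_setequal(out$cell_id, which(epi))
  thr <- attr(out, "gate_report")$thresholds
  expect_true(all(thr > 10 & thr < 100))  # threshold lies between the modes
})

test_that("fixed permissive gates pass everything; empty gates error", {
  tab <- make_qc_table(40)
  spec_ok <- normalization_spec(gate_method = "fixed",
                                gate_thresholds = c(CK8 = 0, `E-Cad` = 0))
  expect_equal(nrow(gate_epithelial(tab, spec_ok)), 40L)
  spec_bad <- normalization_spec(gate_method = "fixed",
                                 gate_thresholds = c(CK8 = 1e9, `E-Cad` = 1e9))
  expect_error(gate_epithelial(tab, spec_bad), "every cell")
})

test_that("z-scoring is anchored on the control median and sample SD", {
  tab <- make_cell_table(
    data.frame(cell_id = 1:5, nuclear_size = 40,
               M1 = c(0, 0, 10, 10, 10), AF_Cy3 = 0,
               dta = c(1, 1, 1, 1, 2),
               cohort = c("control", "control", "control", "control",
                          "treated")),
    intensity_cols = c("M1", "AF_Cy3"), wavelengths = c(M1 = "Cy3"),
    exposures = c(M1 = 1, AF_Cy3 = 1))
  out <- zscore_to_control(tab, normalization_spec(), columns = "M1")
  # hand oracle: control {0,0,10,10} has median 5, sample SD sqrt(100/3)
  expect_equal(out$M1[5], (10 - 5) / sqrt(100 / 3), tolerance = 1e-12)
  expect_equal(out$M1[1], (0 - 5) / sqrt(100 / 3), tolerance = 1e-12)
  # a cell at the control median lands exactly at zero
  tab$dta <- c(0, 2, 4, 6, 2)
  mid <- zscore_to_control(tab[c(1, 2, 3, 5), ], normalization_spec(),
                           columns = "dta")
  expect_identical(mid$dta[2], 0)
  expect_error(zscore_to_control(tab, normalization_spec(),
                                 columns = "AF_Cy3"), "zero")
  expect_error(zscore_to_control(tab, normalization_spec(control_label = "x"),
                                 columns = "M1"), "control")
})

test_that("control-cohort medians are zero after z-scoring every column", {
  tab <- make_qc_table(101, seed = 31)  # odd control count: exact zero median
  out <- zscore_to_control(tab, normalization_spec())
  ctrl <- out$cohort == "control"
  for (col in c("CK8", "E-Cad", "EGFR", "dta"))
    expect_identical(median(out[[col]][ctrl]), 0)
})

test_that("the QC chain preserves cell identity without duplicates", {
  tab <- make_qc_table(400, seed = 12)
  out <- qc_normalize(tab, normalization_spec())
  expect_true(all(out$cell_id %in% tab$cell_id))
  expect_false(any(duplicated(out$cell_id)))
  expect_lt(nrow(out), nrow(tab))
  chain <- attr(out, "qc_chain")
  expect_named(chain, c("outliers", "gate", "control_stats"))
})
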