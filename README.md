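# tripodd

Quantifying how much of a drug's target is still available for binding —
directly in tissue, cell by cell.

`tripodd` is an R toolkit for **paired-agent imaging** combined with
**cyclic immunofluorescence (cyCIF)**. In paired-agent imaging, a
fluorescent *targeted* drug derivative and a spectrally distinct
*untargeted* derivative are co-administered: both accumulate nonspecifically,
but only the targeted probe also binds the drug's target. The package turns
the two probe channels into a per-pixel **drug target availability (DTA)**
map, aligns it with a multi-round cyCIF marker stack, and produces QC'd,
control-normalized single-cell tables and cohort statistics. A synthetic
tissue phantom with known per-cell ground truth makes the whole chain
testable without any external data.

## The core quantity

For each pixel with targeted intensity `I_T` and untargeted intensity
`I_UnT`,

```
DTA = SF * (I_T / I_UnT) - 1
```

where the scaling factor `SF` is the ratio of the untargeted to the
targeted probe's fluorescence-per-concentration slope, fitted from a
titration series. `SF * I_T` and `I_UnT` are then in common concentration
units, so `DTA` is the specific (bound) signal in units of the nonspecific
background — it scales with `(1 - f)` when the unlabeled parent drug
occupies a fraction `f` of target sites, making it a target-engagement
readout.

Around that core the package provides, module by module:

| Stage | Functions |
|---|---|
| Phantom with ground truth | `phantom_config()`, `generate_phantom()`, `generate_titration()` |
| Calibration | `fit_titration()`, `compute_scaling_factor()`, `calibrate_sf()` |
| DTA mapping | `make_tissue_mask()`, `compute_dta_map()`, `summarize_region()` |
| Registration | `register_rounds()`, `register_control_points()`, `apply_transform()` |
| Single cells | `segment_nuclei()`, `extract_features()` |
| QC / normalization | `normalize_exposure()`, `subtract_autofluorescence()`, `filter_outliers()`, `gate_epithelial()`, `zscore_to_control()`, `qc_normalize()` |
| Statistics | `relative_values()`, `pearson_cor()`, `anova_lsd()`, `cohort_summary()` |
| I/O and pipeline | `load_stack()`, `write_phantom()`, `process_tissue()`, `run_pipeline()` |

A thin command-line front end over the same functions is installed at
`inst/cli/tripodd.R` (`Rscript tripodd.R phantom|calibrate|dta|register|
segment|quantify|qc|stats|run ...`).

## Worked example

Calibrate the scaling factor from a titration series, then run the full
pipeline on a paired phantom study — an untreated control tissue and a
tissue in which the parent drug occupies half the target sites:

```r
library(tripodd)

tit <- generate_titration(slope_T = 3, slope_UnT = 6,
                          concentrations = c(1, 2, 4, 8, 16, 32),
                          noise_sigma = 1.9, seed = 42)
sf <- calibrate_sf(tit$series)
sf
#> <scaling_factor> SF = 1.9990 (slope_UnT 5.9985 / slope_T 3.0007; r2 1.000 / 1.000)

study <- list(
  tissues = list(
    list(id = "ctrl", cohort = "control",
         phantom = phantom_config(n_cells = 100, field_size = c(384, 384),
                                  seed = 7),
         phantom_seeded = TRUE),
    list(id = "trt", cohort = "treated",
         phantom = phantom_config(n_cells = 100, field_size = c(384, 384),
                                  occupancy_f = 0.5, seed = 7),
         phantom_seeded = TRUE)),
  titration = tit$series, seed = 1)

run <- run_pipeline(study)
run
#> <tripodd_run> SF 1.9990; 2 tissues; 200 cells raw -> 140 after QC
run$stats$anova_dta
#> <stat_result> one-way ANOVA + Fisher LSD: F(1, 138) = 62.46, p = 7.752e-13
#>   pairwise (LSD):
#>     control vs treated: diff 1.057, p = 7.752e-13 ****

med <- vapply(split(run$cells_raw$dta, run$cells_raw$cohort),
              median, 0, na.rm = TRUE)
sprintf("cohort median DTA: control %.3f, treated %.3f (ratio %.3f)",
        med[["control"]], med[["treated"]], med[["treated"]] / med[["control"]])
#> "cohort median DTA: control 0.850, treated 0.427 (ratio 0.503)"
```

Reading the numbers: the recovered `SF` is within 0.1% of the true gain
ratio (6/3 = 2). After registration, segmentation and QC, 140 of 200 cells
survive the autofluorescence/size filters and the CK8+E-Cad epithelial
gate. The treated cohort's median cell DTA is 0.503 of the control's —
the phantom was built with 50% target occupancy, and the ratiometric
readout recovers exactly that. The ANOVA-with-LSD layer flags the cohort
difference on the z-scored DTA at p < 1e-12.

The methods vignette (`vignettes/tripodd-methods.Rmd`) documents the model,
the QC conventions, the phantom's forward model and its limits.

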