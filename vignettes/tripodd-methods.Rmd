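---
title: "Methods: ratiometric drug-target-availability mapping with multiplexed single-cell readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric drug-target-availability mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripodd)
```

## The measurement problem

A targeted small-molecule drug derivative carrying a fluorophore accumulates
in tissue both by binding its target and by nonspecific uptake. Co-injecting
a spectrally distinct *untargeted* derivative — identical pharmacology minus
target binding — gives a per-pixel reference for the nonspecific component,
so the specific (bound) excess can be isolated ratiometrically. `tripodd`
implements this paired-agent readout and the surrounding single-cell
pipeline: calibration, per-pixel drug target availability (DTA) maps,
registration of cyclic immunofluorescence (cyCIF) rounds, nuclear
segmentation and feature extraction, QC/normalization, and cohort
statistics.

## The DTA model

For a pixel with targeted intensity $I_T$ and untargeted intensity
$I_{UnT}$,

$$\mathrm{DTA} = SF \cdot \frac{I_T}{I_{UnT}} - 1 .$$

The scaling factor $SF$ is the ratio of the two probes'
fluorescence-per-concentration gains, measured by imaging each probe at
titrated concentrations, fitting an ordinary least-squares trend line per
probe, and taking slope(untargeted)/slope(targeted). $SF \cdot I_T$ and
$I_{UnT}$ are then both in untargeted-equivalent concentration units, so
the ratio minus one is the bound excess relative to nonspecific uptake — a
binding-potential-style quantity. When the unlabeled parent drug occupies a
fraction $f$ of target sites, the specific signal and hence DTA scale by
$(1-f)$, which is what makes the map a target-engagement readout.

Two conventions are deliberate and configurable:

* **Intercepts are fitted, not forced through zero**, and only slopes enter
  $SF$. Autofluorescence or detector offset lands in the intercept instead
  of biasing the gain.
* **Scaling-factor placement.** `compute_dta_map(..., sf_on = "targeted")`
  (default) multiplies $I_T$ by $SF$ with $SF$ defined as the
  untargeted/targeted slope ratio. For calibrations defined the other way
  round, `sf_on = "untargeted"` computes $I_T/(SF \cdot I_{UnT}) - 1$.

DTA is undefined where the denominator is at noise level; pixels with
$I_{UnT} \le$ `floor_eps` (or outside the tissue mask) are flagged invalid
and excluded from every summary. `floor_eps` defaults to a small positive
constant; `floor_from_reference()` derives it as the 95th percentile of a
vehicle/autofluorescence reference image when one is available. Negative
DTA values are retained, never clipped.

## Tissue masking

Manual tissue outlining is replaced by automatic thresholding of a
reference channel. The threshold is found by Otsu's method **on
log-intensities**: fluorescence slides have three populations (slide
background, dim tissue matrix, bright cells) and a linear-scale Otsu tends
to split off only the bright cells, whereas the log transform compresses
the cell tail and separates slide from tissue. The largest connected
foreground component is kept and holes are filled. Externally drawn masks
can be imported unchanged (provenance `"imported"`).

## Registration

cyCIF rounds are aligned on their DAPI channels by phase correlation: the
normalized cross-power spectrum concentrates the alignment into one
correlation peak at the round's rigid shift, refined to sub-pixel precision
by parabolic interpolation of the peak and its neighbors. The peak height
(1 for a perfect shift, near 0 for unrelated images) is the confidence
score; registrations scoring below `min_score` (default 0.1, an order of
magnitude above the null-peak level of structureless image pairs) raise an
error so the round can be flagged rather than silently mis-aligned. The
default motion model is translation-only — serial rounds of one mounted
section shift but rarely rotate — with an optional coarse rotation search.
Resampling is bilinear, with out-of-field pixels zero-filled and tracked in
a validity mask.

The DTA-to-marker alignment defaults to the identity (the same physical
section is imaged in both workflows); a manual-correction path fits a
least-squares rigid transform (orthogonal Procrustes, reflection excluded)
to user-supplied control-point pairs, reporting the residual RMS.

## Segmentation and feature extraction

Nuclei are segmented from DAPI by Otsu thresholding, hole filling, and a
distance-transform watershed that splits touching nuclei; components below
`min_area_px` (default 20 px) are dropped. Per-cell features are the
nuclear area, centroid, and the mean of every registered channel over the
nuclear mask dilated by `cell_expansion_px` (default 3 px) to capture
cytoplasmic signal. Cell DTA is the mean of valid DTA pixels in that
expanded mask (the DTA map is treated as one more channel), with the
valid-pixel fraction recorded.

Contested expansion pixels are resolved by **nearest nucleus** (geodesic
Voronoi growth of the labels). A nearest-*centroid* rule was considered
and rejected: with unequal nuclear radii it can assign a ring pixel of a
large nucleus to a smaller neighbor whose centroid happens to be closer,
leaking signal across cell boundaries; for similarly sized disks the two
rules agree.

## QC and normalization

The chain runs in a fixed order, mirroring how the quantities are defined:

1. **Exposure normalization** — every marker and autofluorescence mean is
   divided by its channel's exposure time (a.u./ms).
2. **Autofluorescence subtraction** — each marker has the same cell's AF
   mean for the marker's wavelength subtracted; negatives are retained.
3. **Outlier filtering** — cells strictly above the 95th quantile of Cy3
   autofluorescence are removed (likely tissue artifacts), and cells with
   nuclear size strictly below the 5th or above the 95th quantile are
   removed (likely mis-segmentations in a tissue of similarly sized cells).
   Thresholds are linear-interpolation quantiles (R type 7, the common
   default across numerics stacks) computed **once on the input table**, so
   re-filtering the output at the same thresholds removes nothing.
4. **Epithelial gating** — cells must be positive for both CK8 and
   E-Cadherin to count as tumor cells. No threshold is prescribed by the
   protocol, so the default is Otsu on log1p-transformed values across the
   cohort, with a fixed-threshold override.
5. **Control-anchored z-scoring** — each biomarker column and the DTA are
   centered on the median and scaled by the standard deviation of the
   untreated-control cells. The SD is the sample SD (ddof = 1); whether
   the original convention was population or sample SD is unstated, so the
   choice is documented rather than inferred. A constant control column is
   an error, not a silent NaN.

After z-scoring the control cohort's median is 0 by construction — exactly
0 when the control count is odd (the median is an observed value), and to
within one floating-point rounding of the two-middle-value average when it
is even.

## Statistics

Tissue- or cohort-level comparisons use one-way ANOVA with Fisher's LSD
post-hoc tests at $\alpha = 0.05$: pairwise t-tests sharing the pooled
within-group mean square and its residual degrees of freedom, with no
further multiplicity adjustment (that is the definition of LSD). The
default is the *unprotected* variant — pairwise tests regardless of the
omnibus F — since the original software's behavior is not documented;
`protected = TRUE` gates them on omnibus significance. The F statistic is
computed from the between/within sums-of-squares decomposition (which the
LSD needs anyway); the test suite cross-checks it against `stats::aov` and
a from-scratch oracle, and verifies the empirical type-I error at
$\alpha = 0.05$ over 10,000 null simulations. Pearson correlations report
$r$, a two-sided p-value from the $t$-distribution on $n-2$ degrees of
freedom, and the least-squares trend line for scatter export. Relative
intensity/DTA values divide each tissue mean by the cohort maximum.
Box-plot exports use Tukey whiskers (1.5 IQR), the plotting convention the
summaries are meant to feed.

Whether tumors or tissue sections are the independent unit is a study
design question the package does not decide: `anova_lsd()` takes whatever
grouping the caller supplies, so the unit of analysis is explicit at the
call site.

## The synthetic phantom

`generate_phantom()` builds a ground-truthed stand-in for a xenograft
section. Nuclei are non-overlapping disks (radius $\sim N(6, 1)$ px) placed
by rejection sampling inside an elliptical tissue region, each with a 4-px
cytoplasmic annulus; the whole cell footprint carries the probe and marker
signal. The footprint is uniform per cell so that means over any subregion
of a cell equal the per-cell truth — this is what makes exact oracles
possible. Per cell, receptor density $R$ and nonspecific uptake $N$ are
log-normal (median 50, sdlog 0.35 and 0.30); the targeted channel is
$s_T(B(1-f)R + N)$ and the untargeted channel $s_{UnT} N$ inside cells,
with gains $(s_T, s_{UnT}) = (3, 6)$, binding gain $B = 1$, and a uniform
background uptake in the tissue matrix. True per-cell DTA is
$B(1-f)R/N$ and the true scaling factor $s_{UnT}/s_T = 2$. Autofluorescence
(mean 2 a.u. per wavelength — small against ~300 a.u. probe signal,
emulating the optimal-dose regime), truncated-Gaussian noise
($\sigma = 2$; Poisson shot noise optional), per-round rigid shifts, and a
cyCIF marker panel (epithelial CK8/E-Cad high in the ~90% tumor fraction
and low in stroma; EGFR/pEGFR proportional to $R$; bimodal CC3 with a ~10%
apoptotic-positive subset) complete the forward model. Everything is
reproducible bit-for-bit from the config seed.

What the phantom does **not** emulate: optical point-spread, illumination
shading, spectral bleed-through, tile stitching, irregular nuclear shapes,
overlapping or out-of-focus cells, and spatially structured biology.
Passing phantom tests therefore demonstrates that the *computational*
chain is correct — equations, filters, registrations, statistics — not
that segmentation or masking would reach the same accuracy on real tissue.

## Numerical choices and problem sizes

* Quantiles everywhere are linear-interpolation (type 7).
* Sub-pixel registration uses parabolic peak interpolation, accurate to
  well under 0.5 px on the phantoms; bilinear interpolation for warps.
* Float TIFF output is scaled into $[0,1]$ by power-of-two scale/offset
  recorded in a JSON sidecar: the mapping is an exponent shift, so decoded
  values are stable across repeated write/read cycles to within the
  writer's 32-bit quantization step.
* Degenerate inputs fail loudly by design: empty masks, constant control
  columns, non-positive calibration slopes, sub-floor denominators and
  unregisterable rounds all raise errors naming the condition.
* The test and acceptance workloads use phantoms of 200 cells (640 px
  field) for DTA-oracle checks, 500 cells (1024 px) per occupancy level,
  and paired 50-cell tissues for end-to-end determinism — sizes chosen so
  each property is measured at meaningful cell counts while a full run
  stays interactive on a laptop.

## Known limitations

* The DTA equation assumes the two probes share pharmacokinetics apart
  from binding; the phantom enforces this by construction, real tissues
  only approximate it.
* The forward model (uniform per-cell signal, additive truncated-Gaussian
  noise, log-normal uptake) is an enabling assumption: no quantitative
  uptake or noise model is prescribed by the underlying protocol.
* Registration is rigid; deformable distortion between rounds is out of
  scope.
* The epithelial gate is a two-marker threshold, not a cell-type
  classifier.
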