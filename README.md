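# carpelseg

Phenotyping of **unpollinated wheat carpels** from RGB stereo-microscopy
images. In the absence of pollination the feathery stigma expands, peaks and
then collapses, while the unfertilised ovary swells radially and plateaus;
how long a male-sterile (MS) cultivar's carpels stay receptive is a key
trait for hybrid seed production. Measuring it means outlining stigma and
ovary in hundreds of carpel images — the manual bottleneck this package
removes.

The package is aimed at cereal-breeding and floral-development researchers
and provides the full pipeline:

* **Segmentation** — small encoder–decoder convolutional networks (U-Net
  style) trained with a soft Dice loss, `1 − (2Σpt + 1)/(Σp + Σt + 1)`, and
  Adam updates; one network predicts the stigma-hair envelope, a second
  predicts ovary + stigma masks. Convolutions are lowered to BLAS GEMM
  kernels (Rcpp/Armadillo), so training runs in minutes on one CPU.
* **Morphometry** — stigma area as the pixel count × (mm/px)²; ovary
  diameter as the chord through the ovary centroid **perpendicular to the
  carpel's long axis** (the line through the stigma and ovary centroids),
  found by sub-pixel marching to the mask boundary and converted to mm with
  the per-image scale.
* **Validation** — Dice similarity coefficient, DSC = 2|A∩B|/(|A|+|B|),
  per image and summarised by developmental stage × fixation.
* **Time courses** — IQR outlier filtering (1.5×IQR Tukey fences,
  interpolated quartiles), Loess smoothing (span 0.9, 95% band), cumulative
  degree days above a 0 °C base, classification into growth / peak /
  deterioration phases (85% rise, 15% drop, 40% drop of the smoothed
  stigma-area maximum; end = last sampling), and cultivar ranking from slow
  to fast.
* **Synthetic data** — seeded generators for carpel scenes with ground-truth
  masks, per-carpel trait trajectories with known phase boundaries, and
  daily temperature series, so everything above is testable without any
  download.

See `vignettes/carpel-phenotyping.Rmd` for the model, the parameter
conventions and the design decisions.

## Worked example

Generate a synthetic cultivar trio with different post-peak decline rates,
run the analysis, and rank them:

```r
library(carpelseg)

declines <- c(BSS1 = 0.05, `24512` = 0.10, `24522` = 0.20)  # day^-1
reports <- lapply(names(declines), function(cv) {
  p  <- trajectory_params(cultivar_id = cv, decline_rate = declines[[cv]],
                          timepoints = c(0, 3, 7, 13, 18, 24))
  ts <- generate_trajectory_set(p, seed = 42)
  rec  <- ts$records
  keep <- iqr_filter(rec$stigma_area_mm2, rec$timepoint_days)$keep
  sc   <- loess_smooth(rec$timepoint_days[keep], rec$stigma_area_mm2[keep],
                       span = 0.9, grid = seq(0, 24, by = 0.1))
  classify_phases(sc, temperature = generate_temperature_series(30, seed = 1),
                  last_sampling = 24, cultivar = cv)
})
reports[[1]]
rank_cultivars(reports)
```

```
<phase_report> BSS1: growth end 4.26 d, peak 8.30-11.52 d, 40% drop 17.83 d, end 24.0 d
  cultivar peak_end deterioration_marker_40pct rank speed_class
1     BSS1 11.52393                   17.83247    1        slow
2    24512 10.79925                   13.32088    2    moderate
3    24522 10.01363                   11.62255    3        fast
```

The phase report reads: this cultivar's stigma reached 85% of its maximum
area ~4.3 days after W9.5 (end of the growth phase), peaked at ~8.3 days,
dropped 15% below the maximum at ~11.5 days (onset of deterioration) and
40% below at ~17.8 days. Ranking by the onset of deterioration labels the
three cultivars slow / moderate / fast — recovering the ordering of the
decline rates they were generated with. Thermal-time durations are carried
alongside: for this cultivar the growth / peak / deterioration phases span
76.2 / 142.8 / 244.9 degree days (°C·day, base 0 °C) under the synthetic
season used in the example (`reports[[1]]$durations_degree_days`).

The segmentation half has the same shape: `generate_carpel_batch()` renders
scenes + ground truth, `train_segmenter()` fits a network, `predict_masks()`
+ `postprocess_mask()` produce masks, `measure_batch()` writes the
measurement table, and `cross_validate()` scores agreement with Dice. The
`inst/cli/carpel.R` script chains everything
(`generate → train → segment → measure → validate → phases → rank`).

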