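# sticsflow

Quantify **superimposed protein flows** in fluorescence image time series by
spatially filtering the series before **spatiotemporal image correlation
spectroscopy (STICS)**.

Live-cell recordings of cytoskeletal proteins (nonmuscle myosin II along
actomyosin bundles, F-actin in podosome clusters, ...) often contain two
kinds of correlated intensity fluctuation at once:

* **contiguous flow** — labeled structures physically move, carrying their
  intensity profile with them;
* **noncontiguous flow** — a wave of intensity travels across structures
  that barely move, as molecules exchange between neighboring complexes.

STICS correlates the intensity fluctuations `delta i` of a small region of
interest (ROI) with the same region at later times,

```
r(xi, eta, tau) = < delta_i_t(x, y) * delta_i_(t+tau)(x + xi, y + eta) >
                  / (N_pix <i_t> <i_(t+tau)>)
```

and converts the displacement of the correlation peak versus time lag `tau`
into a velocity vector per ROI. When both flow types overlap they mix in the
ensemble correlation (brightness enters quadratically), so this package
filters each frame first:

* `gaussian_filter(series, sigma)` — widens the effective PSF, erasing
  structure-scale texture; STICS then reports the **noncontiguous** flow.
* `heterogeneity_map(series, d)` — the new filter: `HM = (I - mu) / mu`,
  with `mu` the local mean under a circular kernel of diameter `d`. It
  accentuates each pixel's contrast against its neighborhood independent of
  absolute brightness (`HM(c I) = HM(I)`); STICS then reports the
  **contiguous** flow.

The package also ships the two-layer flow simulator used to validate the
approach (drifting point emitters + a traveling wide-PSF intensity wave,
with exact ground truth), Fourier-based translational registration, the
full FFT STICS engine with immobile-fraction subtraction, Gaussian
correlation-peak tracking and vector quality flags, and vector-field
summary statistics (mean/median/max speed, median-cosine alignment
percentages).

## Worked example

Simulate the contiguous-only preset (200 point emitters, 100 x 100 px at
0.14 um/px, drifting rightward at 0.5 um/min, 30 frames at 15 s) and run
STICS with the default parameters (ROI 32 px / shift 4, TOI 5 frames /
shift 1, lags 1-4):

```r
library(sticsflow)

sim <- simulate_series(default_sim_config("contiguous", seed = 1))
sim$series
#> image_series: 30 frame(s) of 100 x 100 px | 0.14 um/px, 15 s/frame | simulated

res <- stics_analyze(sim$series, stics_params())
res
#> stics_result: 26 TOI(s) x 324 ROI(s); 7714/8424 valid vectors
#>   mean valid speed 0.493 um/min, mean angle 0.187 deg

summarize_field(bind_fields(res))
#>   n_valid mean_speed median_speed max_speed alignment_pct_horizontal alignment_pct_vertical
#> 1    7714      0.493        0.494      0.61                   99.958                  0.465
```

The configured drift was 0.5 um/min rightward: STICS recovers a mean valid
speed of 0.493 um/min (-1.4%) with 99.96% median-cosine alignment to the
horizontal axis (100% = perfect alignment, 0% = orthogonal). The run takes
about 1.5 minutes on one core. For a mixed video
(`default_sim_config("mixed_multiply")`), apply `apply_filter(series,
"gaussian")` and `apply_filter(series, "heterogeneity")` and analyze each
branch: the Gaussian branch reports the vertical intensity wave and the
heterogeneity branch the horizontal particle drift.

A command-line front end covering simulate / register / filter / stics /
metrics / pipeline lives in `inst/scripts/sticsflow.R`; `run_pipeline()`
drives the whole chain from a YAML config and writes filtered TIFFs, vector
CSVs, per-TOI summary CSVs and a reproducibility manifest.

See `vignettes/superimposed-flows.Rmd` for the model, parameter guidance,
numerical choices and known limitations.

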