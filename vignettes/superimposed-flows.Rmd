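---
title: "Separating superimposed protein flows with spatial filtering and STICS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating superimposed protein flows with spatial filtering and STICS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sticsflow)
```

## The problem

Fluorescence image time series of living cells frequently contain several
kinds of correlated intensity fluctuation at once. A *contiguous* flow is the
physical displacement of labeled structures: a myosin punctum or a podosome
moves, carrying its intensity profile with it. A *noncontiguous* flow is a
traveling wave of intensity across structures that barely move: molecules
dissociate from one complex and bind a neighboring one, so one spot dims
while the next brightens. Spatiotemporal image correlation spectroscopy
(STICS) measures flow by correlating the intensity fluctuations of a small
region with the same region at later times and tracking the displacement of
the correlation peak; when both flow types overlap in one recording the
ensemble correlation mixes them, and the brighter component dominates because
intensity enters the correlation quadratically.

The two flow types usually live on different spatial scales — structure
displacement at the scale of the structures themselves, intensity exchange at
the scale of the inter-structure spacing and beyond. This package separates
them by filtering each frame *before* STICS:

* **Gaussian filter** (`gaussian_filter()`): convolving with a wide Gaussian
  computationally enlarges the effective point spread function, erasing
  structure-scale texture while preserving the large-scale intensity
  envelope. STICS on the filtered series reports the noncontiguous flow.
* **Heterogeneity map** (`heterogeneity_map()`): each pixel is normalized to
  the mean intensity of its circular neighborhood,
  `HM = (I - mu) / mu` with `mu = local_mean(I, disk(d))`. A pixel brighter
  than its surroundings scores positive, a dimmer one negative, *regardless
  of absolute brightness*: `HM(c * I) = HM(I)` for any gain `c > 0`. The map
  keeps the local texture that tracks structure displacement and discards
  the global intensity waves. STICS on the map reports the contiguous flow.

## The STICS engine

`stics_analyze()` tiles the series into square regions of interest (ROIs,
default 32 px side, origins every 4 px) and sliding time windows (TOIs,
default 5 frames, advancing 1 frame), and per (ROI, TOI):

1. **Immobile-fraction subtraction** — each pixel's temporal mean is removed
   so static structures do not pin the correlation peak at zero lag. The
   mean is taken over the *whole series* by default. This choice matters:
   a mean estimated from only the 5 frames of a TOI is strongly correlated
   with the moving signal itself, and correlating the residuals then
   displaces the peak systematically (on a clean translating spot the
   apparent displacement becomes `2 * tau - 1` pixels instead of `tau`,
   i.e. recovered speeds double). With the whole-series mean the subtracted
   "streak" is long and dilute and the bias is negligible.
   `stics_params(whole_series_subtraction = FALSE)` restores the per-TOI
   scope for comparison, and `immobile_subtraction = FALSE` disables the
   step — appropriate for short synthetic sequences in which nothing is
   static.
2. **Correlation function** — for each lag `tau = 0..max_lag`, the cyclic
   spatial cross-correlation of the fluctuations of every frame pair
   `(t, t + tau)`, computed with FFTs and averaged over pairs, normalized by
   `N_pix * <i_t> * <i_(t+tau)>` (the means of the intensities, so a global
   gain change cancels). When a spatial mean is at or below
   `1e-9 * max(series)` — routine for heterogeneity maps, whose means are
   near zero — the unnormalized cross-covariance is used instead; this is a
   pure rescaling per lag and cannot move the peak.
3. **Peak tracking** — the lag-1 peak is searched within
   `peak_search_radius` (default `roi_size / 4`, beyond which a cyclic
   correlation becomes ambiguous) of zero lag; each later lag within the
   same radius of the previous center. Each peak is localized by a
   Levenberg-Marquardt fit of an isotropic 2D Gaussian with offset,
   `A * exp(-((xi - xi0)^2 + (eta - eta0)^2) / w^2) + c`, over the square
   window re-centered on the discrete argmax. Two numerical details are
   deliberate: the window is re-centered because an off-center window
   around a correlation dome wider than the window (a Gaussian-filtered
   wave) otherwise biases the fitted center outward by tens of percent; and
   the width is initialized from the window's second moment because sharp
   particle peaks (2-3 px) and broad wave domes (15-20 px) both occur and a
   fixed starting width stalls the optimizer on the wrong regime. Ties in
   the argmax go to the smallest `(eta, xi)` lexicographically.
4. **Velocity regression** — ordinary least squares of peak column lag and
   row lag against `tau` (lags 1..4, with intercept); slopes in px/frame are
   converted to um/min. A vector is kept only if at least
   `min_lags_for_fit = 3` peaks survived, the tracked displacement stayed
   within `roi_size / 4`, and the mean regression R^2 reached
   `r2_threshold = 0.8`; otherwise the vector is retained with `valid =
   FALSE` and an explicit `rejection_reason`. The R^2 of an exactly zero
   residual is defined as 1 so that noiseless constant tracks count as
   perfect.

Angles are mathematical (0 degrees = rightward, +90 = toward the top of the
image); ROI centers are reported in um with y increasing downward from the
top edge.

## The simulator

`simulate_series()` generates the two-layer ground-truth videos used by the
tests and the acceptance script. The defaults of `default_sim_config()` are
the frozen study conditions of the `"two_layer"` preset: a 100 x 100 px
canvas at 0.14 um/px; a *main* layer of 200 point emitters (PSF 1/e^2 radius
0.5 um, i.e. sigma = 0.25 um) placed uniformly at continuous coordinates,
each emitting 400 photons/s, drifting rightward at 0.5 um/min; a *wave*
layer of 100 emitters with a 2 um PSF radius seeded on a horizontal line one
third of the canvas height above the bottom edge, translating upward at
0.5 um/min; 30 frames at 15 s intervals, 1 s exposure, no noise, bleaching
or blinking. Each emitter contributes `A * exp(-2 d^2 / r^2)` sampled at
pixel centers with `A` chosen so the continuous integral equals the photon
budget; profiles are truncated at `2 r` (4 sigma, < 0.04% mass). Layers are
combined by addition, or by multiplication followed by division by the
wave frame's spatial mean so the product stays on the main layer's intensity
scale (only relative fluctuations matter to the correlation).

Choices the source conditions left open, fixed here once:

* **Wave animation.** The wave layer translates rigidly along the vertical.
  A traveling translation is the simplest motion that produces the vertical
  noncontiguous vector field the mixed scenarios require; oscillation or
  amplitude modulation would be alternatives, and only the translation is
  implemented.
* **Boundary behavior** is cyclic (positions wrap, PSF tails wrap), so
  particle density and total intensity are stationary — the clean setting
  for correlation statistics. `boundary = "open"` lets particles leave
  instead.
* **Emitter count.** The stated per-area density and the stated count of
  200 emitters on this canvas disagree by a factor of five; the explicit
  count is used.
* One simulation consumes one seeded RNG stream, layers initialized in a
  fixed order (main, then wave), so a seed pins the video bit-for-bit.

What the simulator does *not* emulate: photon (Poisson) noise, detector
noise, bleaching, blinking, diffusion, 3D PSFs, or cell-shaped intensity
masks. Passing tests on these videos therefore demonstrate the correctness
and calibration of the analysis chain on noiseless rigid flows, not
performance at the signal-to-noise ratios of real recordings.

## Registration

`register_series()` removes whole-frame translation (stage drift, slow cell
movement) by phase correlation against a reference frame (default: the
first; the reference choice is a documented convention, since nonmigratory
cells make the difference immaterial). The cross-power spectrum is
regularized (`|P| + 0.01 max |P|`) before whitening — full whitening
amplifies the noise-dominated high frequencies of smooth images — and frames
are shifted back by integer-pixel cyclic rolls; an optional centroid
refinement reports subpixel shifts. Registration is *off* by default in
`run_pipeline()`: on a rigidly drifting simulation it would cancel the very
flow under study. Register real recordings, then filter, then run STICS.

## Tuning the two filters

* `hm_kernel_diameter` (px) should span one structure of interest plus as
  much of the gap to its neighbors as possible (8 px for ~1 um myosin
  puncta at 0.14 um/px, 16 px for podosomes). Too small highlights
  sub-structure; too large stops emphasizing local heterogeneity.
* `gaussian_sigma` (px, default 7) should exceed the spacing between
  adjacent structures so their intensities merge; too large averages out
  the very fluctuations being measured.
* For STICS itself, the ROI should be a few times larger than the moving
  structure (32 px here; 16 px with 2 px shifts resolves small-structure
  fields more finely at extra cost), and the TOI should span the timescale
  of the motion of interest (5 frames = 75 s at these frame rates).

## Problem sizes and runtime

The reproduction script (`scripts/acceptance.R`) and the heavier end-to-end
tests analyze 100 x 100 px, 30-frame videos at ROI 32 / shift 4 / TOI 5 /
shift 1 — 324 ROIs x 26 TOIs, about 34,000 peak fits — which completes in
roughly 1.5-2 minutes per branch on a single core. The unit tests use
smaller canvases (32-64 px, 5-10 frames) and run in a few minutes. The
Levenberg-
Marquardt stopping tolerances (`ftol 1e-6`, `ptol 1e-4`, 100 iterations)
were set so that fitted centers are stable to well under 0.01 px — an order
of magnitude below the subpixel precision the velocity regression needs.

## Known limitations

* **ROI-edge truncation.** Structures clipped by the ROI boundary bias the
  correlation peak toward zero lag; with 32 px ROIs and 2-3 px-sigma spots
  the net speed bias of the full pipeline is about 1-2%, but analyses of
  patterns whose correlation width approaches the ROI (wave-like envelopes)
  under-estimate speeds by 10-15%. Mean recovered speeds on the wave preset
  are ~0.43 um/min against a 0.5 um/min ground truth. Larger ROIs reduce
  the bias at the cost of spatial resolution.
* **Residual contiguous texture after Gaussian filtering.** A sigma-7
  blur of a ~1 emitter/um^2 point field still leaves ~30% spatial contrast
  moving with the contiguous flow. On multiplicatively mixed videos the
  Gaussian branch therefore still picks up horizontal vectors where the
  wave envelope is weak (especially behind the wave's trailing edge): the
  median vertical alignment saturates around 0.75-0.87 across seeds rather
  than approaching 1, and raising the emitter density does not help. The
  heterogeneity branch is much cleaner in the opposite direction (~0.99
  horizontal alignment), because normalizing away the envelope is exact
  whereas blurring away point texture is only approximate.
* **No rotation or scaling** in registration; translation only.
* **Velocities are linear fits** over at most `max_lag` lags; accelerating
  or curving flows within a TOI are averaged.
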