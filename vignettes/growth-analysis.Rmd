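---
title: "Cell-cycle-resolved growth analysis of asymmetrically dividing bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cycle-resolved growth analysis of asymmetrically dividing bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccgrowth)
```

## The problem

*Caulobacter crescentus* divides asymmetrically into a small, motile swarmer
cell and a larger, surface-attached stalked cell. The swarmer daughter spends
an extended G1 phase — the period between birth and the initiation of DNA
replication, marked operationally by the duplication of fluorescent
replication-marker (MipZ) foci — before differentiating and replicating.
Timelapse phase-contrast imaging yields per-frame cell areas; the scientific
questions are whether the two progeny types grow at different average rates,
whether growth rate varies *within* a cell cycle, and whether any slowdown is
coupled to the G1 phase.

`ccgrowth` implements the full desk-side analysis: per-cell growth metrics
from tracked area trajectories, cell-cycle-unit alignment with bootstrap
confidence bands, G1 quantification from focus counts under two cell-birth
conventions, rule-based progeny classification, explicit trajectory curation,
and a ground-truthed synthetic generator so that every stage can be validated
by parameter recovery.

## Growth metrics

For a cell with area trajectory $A(t)$ sampled every 1.5 min:

* **Smoothing.** Areas are smoothed by a centered sliding average whose
  default 12-frame window corresponds to 18 min. The window is interpreted as
  a half-width of $\lfloor w/2\rfloor$ frames on each side (a 12-frame
  request spans 18 min of trajectory); near the trajectory ends it shrinks
  symmetrically to the frames available rather than padding, so no data are
  invented. The price is that the first and last few rate estimates are
  noisier — downstream consumers (the curation rate bounds, the per-cell
  trough locator) are documented accordingly.
* **Instantaneous relative growth rate.**
  $r_i = (A_{i+1}-A_i)/(A_i\,\Delta t_{\mathrm{frame}})$, in min$^{-1}$,
  computed on the smoothed trajectory. Division by the first area of the pair
  and by the frame interval makes the printed curation bounds
  (min$^{-1}$) directly applicable.
* **Average growth rate.** $\lambda = \ln(A_d/A_b)/\Delta t$ with $A_b$, $A_d$
  the areas at birth and division and $\Delta t$ the interdivision time.
* **Exponential-fit residual score.** A first-degree polynomial is fit to
  $\ln A(t)$ by least squares; the score is the mean over frames of
  $|A - \hat A|/A$ where $\hat A$ is the back-transformed fit. A single
  exponential scores $\approx 0$; a G1-coupled dip inflates the score.

On noiseless exponentials the average rate, the log-linear slope and the
(bias-corrected) mean instantaneous rate agree to $10^{-6}$ relative — the
package's estimator-exactness acceptance experiment.

## Two definitions of cell birth

The classical convention dates birth to the visible separation of the
daughter cells. In *C. crescentus*, however, cytokinesis (one cytoplasm
becoming two) completes substantially earlier — the package's generator uses
an 18 ± 5 min truncated-normal separation delay — so quantities can
alternatively be dated from the moment the mother's mask splits in two.
Field convention marks quantities under the cytokinesis definition with an
asterisk (G1 duration\*, growth rate\*). `assign_birth()` supports both:

* `"cytokinesis"`: birth at the track's first frame (the mask split);
  division at the daughters' first frame; $A_d$ is the cell's area at its
  last frame.
* `"separation"`: birth at the last frame before visible separation;
  division at the frame before the cell's own daughters separate. Because
  tracks in this package split at cytokinesis, the conceptual predivisional
  cell at that point is the union of the two daughter compartments, so $A_d$
  sums the two daughter areas at the pre-separation frame.

With the separation convention most stalked progenies show no G1 at all
(replication starts in the mother compartment); under the cytokinesis
convention nearly all have a positive G1\*. The test suite asserts this
ordering on synthetic data rather than any exact fraction.

## G1 quantification and focus detection

G1 ends at the first fluorescence frame, at or after birth, showing at least
two replication-marker foci; the duration is reported at the 3-min
fluorescence frame resolution, with no interpolation between frames. If the
first observed frame already shows two foci, the duration is 0 ("no G1"
category); if two foci never appear before division the value is flagged
censored. A config switch to require persistence of the two-focus state for
more than one frame was considered and left off by default: on synthetic
data the first qualifying frame recovers the true duration within one frame
for >90% of cells, and a persistence requirement only biases durations
upward at this noise level.

Detection of diffraction-limited foci uses the standard parameter-light
recipe: a difference-of-Gaussians band-pass at the PSF scale
($\sigma$ and $2\sigma$), per-cell robust thresholding of the response
(median + $k\times$MAD within the mask, default $k=5$), greedy merging of
maxima closer than `min_separation` px keeping the brighter, and integrated
disc intensity minus cell-median background as brightness. One addition
proved necessary: a rod-shaped mask produces band-pass ridge maxima at its
poles (cap curvature lives at the PSF scale), which a response-only
threshold cannot reject in low-noise images. Candidates must therefore also
clear the cell background by $k$ photon-noise standard deviations in the
*raw* image (`peak > median + k\sqrt{median}`), the usual companion
criterion. All three parameters are config-exposed.

Polar-marker localization is classified per cell from the foci's coordinates
along the mask's principal axis: positions within `pole_fraction` (default
0.2; no published value exists, so a round fifth of the cell length) of
either end are polar; both poles occupied is bipolar, one is unipolar.

## Alignment, population curves, tempograms

Each inter-frame rate step is mapped to normalized cell-cycle time
(0 = birth, 1 = division) at its midpoint and averaged within 30 equal-width
bins (the bin count is a package default; empty bins stay missing). The
population curve is the per-bin mean over cells with a percentile bootstrap
band from resampling *cells* (n = 1000 draws, 95% by default) — never
individual bins, which would break within-cell correlation. Bins with fewer
than two contributing cells get no interval. Tempograms stack the per-cell
aligned vectors as rows sorted by interdivision time, shortest first.
Alignment is scale-free: rescaling all times leaves the binned vectors
unchanged.

## Curation

The explicit trajectory filters, with strict inequalities so boundary values
are retained: interdivision time < 30 min; total area increase
< 0.61 µm²; any smoothed instantaneous rate > 0.015 min⁻¹ or
< −0.0025 min⁻¹; missing mother or daughters; uncertain progeny type; and,
when enabled for strain comparisons, birth on the pad later than 60 min.
Rate bounds are evaluated on the smoothed series because the rates
themselves are computed from smoothed areas. Every rejection carries one
reason code per failed rule; curation is idempotent and monotone in each
threshold (tested properties). Manual removals are supported only as an
explicit exclusion list in the config, never hard-coded. The 0.61 µm² rule
is implemented as the fixed printed constant rather than a population
statistic.

## Progeny classification

The field classifies progenies visually: stalked if a stalk is visible or if
the sister swims away; swarmer if the cell itself is motile and stalk-free.
The mechanized proxy is net centroid displacement over the three frames
after separation, against a 1 µm threshold (both config-exposed). When both
stalk-free siblings move, or neither does, the cell is `uncertain` and is
dropped downstream — ties are not guessed. On immobilizing (1% agarose-style)
data classification falls back to the stalk flag alone.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, with
every parameter config-exposed and ground truth recorded per cell:

* **Growth.** Exponential baseline µ0 = 0.0077 min⁻¹ (ln 2 over a 90-min
  doubling time, typical of rich-medium growth at 30 °C) with a
  piecewise-linear G1-coupled dip: decline from µ0 at birth to µ0(1−d) at
  the trough, linear recovery over 30 min, constant µ0 after. The paper-level
  curves constrain neither the functional form nor the exact trough time, so
  the simplest monotone shape is used and the trough offset relative to G1
  end is a parameter (default 0).
* **Dip depth scales with G1.** A cell's depth is
  $d_i = d\min(1, g_i/40\,\mathrm{min})$. With a constant depth, short-G1
  cells would show a *deeper* smeared early-cycle dip than long-G1 cells
  (fast decline plus recovery inside the first third), inverting the
  empirical pattern that longer G1 means more pronounced slowing; the
  saturating form reproduces it. Set `dip_g1_scale = 0` for a fixed depth.
* **G1 durations.** Gamma with type-specific means (swarmer 40 min, stalked
  12 min, CV 0.5) — positive support and right skew match observed
  histograms.
* **Division.** Asymmetric split of the mother's area (swarmer fraction
  0.45), triggered at a drawn interdivision time (100 ± 15 min, floored);
  adder/sizer size control is out of scope. Area is conserved exactly at
  each division.
* **Events.** Cytokinesis precedes visible separation by a truncated-normal
  18 ± 5 min delay; tracks split at cytokinesis; `sep_event` flags the last
  frame before separation. Swarmer daughters relocate over the three frames
  after separation; stalked daughters stay.
* **Measurement noise.** Multiplicative lognormal on area, CV 0.4% — the
  sub-pixel boundary-jitter scale of segmentation masks (a ~500 px cell), and
  the level at which the printed curation rate bounds flag only genuine
  artifacts.
* **Foci.** One polar focus before G1 end, two after, the second migrating
  to the far pole over 15 min; sampled on the 3-min fluorescence grid.
  Rendering draws rod masks (rectangle plus cap semicircles), adds diffuse
  cytoplasmic signal and isotropic Gaussian foci, and applies Poisson (or
  Gaussian) noise; 16-bit TIFF stacks round-trip losslessly.

What the generator does **not** emulate: phase-contrast optics and
segmentation itself (masks are taken as given), stalk morphology, motility
physics, drift, cell crowding and mask overlap errors, focus blinking or
proximity interference between neighbouring cells, and any molecular
((p)ppGpp) mechanism — perturbations of that kind are expressed only as
altered G1-mean/dip parameters. Passing the recovery experiments therefore
validates the *analysis logic* under the stated noise model, not performance
on raw microscope data.

## Numerical and design choices

* Frames are 0-based; times are frames × interval. All random draws sit
  behind explicit seeds; identical config + seed reproduce outputs
  byte-for-byte (tested).
* Exact Mann–Whitney enumeration when $n_1+n_2 \le 12$ with no ties, normal
  approximation with tie correction otherwise; asymptotic two-sample KS;
  percentile (not BCa) bootstrap for simplicity and determinism.
* G1 binning intervals are lower-inclusive, upper-exclusive, with the
  largest upper edge closed; cells outside all intervals are excluded with a
  logged reason; tertile edges are provided for three-group comparisons.
* The per-cell trough locator ignores the two edge bins, which average the
  shrunken-window trajectory-end steps.
* Degenerate inputs error early and namedly: non-positive areas, zero-length
  cycles, mismatched image shapes, duplicated (cell, frame) keys, unknown
  config keys, >2 daughters per division.

## Problem sizes

The shipped experiments use 200 founders × 3 generations (400 complete
cells) for parameter recovery, 40 founders for the flat (dip-free) control,
8 founders × 3 generations rendered to ~100 fluorescence frames for the
detection round-trip, and 500 replicates (n = 50, 1000 resamples) for
bootstrap coverage — sizes at which every recovery experiment is stable
across seeds while the whole suite runs in about a minute.

## Known limitations

* Separation-mode metrics on cytokinesis-split tables reconstruct the
  predivisional cell by summing daughter compartments; a tracker that never
  splits early would measure the same cell slightly differently at the mask
  boundary.
* The residual score is reported per cell without normalizing for trajectory
  length; comparisons should hold length distributions comparable (the
  curation minimum-duration rule does this in practice).
* `uncertain` classification absorbs all motion ties; no attempt is made to
  break them with trajectory history.
* The generator draws interdivision times independently of G1 (apart from a
  floor), so G1/cycle-length correlations beyond the programmed dip are not
  emulated.
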