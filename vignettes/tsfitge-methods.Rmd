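---
title: "TS-FITGE analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TS-FITGE analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsfitge)
```

# The measurement model

A TS-FITGE experiment produces one three-channel 2D gel per denaturation
temperature. The channels carry distinct populations of the same cellular
proteome:

* **Cy2** — the *unheated* proteome, loaded in equal amount on every gel.
  It is the internal standard: heat-independent by construction, so it
  reports per-gel loading and imaging gain.
* **Cy3** — the vehicle-treated, heated proteome.
* **Cy5** — the drug-treated, heated proteome.

The quantity of interest per protein and temperature is the soluble
fraction that survived heating. We model denaturation with a
three-parameter logistic in temperature,

$$f(T) = p + \frac{1 - p}{1 + e^{k (T - T_m)}},$$

where $T_m$ is the melting midpoint (degC), $k > 0$ the steepness
(per degC) and $p \in [0, 0.3]$ a non-denaturable floor. This is the
simplest sigmoid with a plateau and matches standard practice for cellular
thermal shift and thermal proteome profiling data; the source experiments
show sigmoidal curves but prescribe no functional form, so the choice is
ours. Drug engagement shifts the midpoint of a target protein by a signed
$\Delta T_m$ (positive = stabilized); all other parameters are shared
between the arms.

## Assumptions

* The internal standard is perfectly heat-independent and per-gel gain is
  a single multiplicative factor common to all three channels. Under these
  two assumptions the normalization below cancels gain *exactly*; real
  dye- or scanner-specific gain differences would leave a residual.
* Drug treatment is short enough that expression-level changes are
  negligible; colored spots in the unheated gel therefore indicate
  post-translational modification (PTM) or image artifacts, not abundance
  changes.
* A PTM shifts the isoelectric point but not the melting behaviour of the
  modified form, and only the drug arm carries it.

# Stage by stage

## Background correction and spot detection

Backgrounds are removed per channel by grayscale morphological opening
with a disc (radius 8 px by default, i.e. > 3 spot sigma), which flattens
smooth illumination while leaving compact spots intact. Detection then
operates on the *pixelwise maximum of the three smoothed channels*: a
protein visible in only one channel (a PTM satellite, a fully destabilized
protein, or the Cy2-only remnant of a melted protein) is still a full-height
peak in the max image. We smooth each channel *before* taking the maximum:
smoothing afterwards would fuse the closely spaced two-peak signature that
channel misregistration produces, and that signature is exactly what the
artifact rule must see.

Peaks are local maxima above `median + min_snr * MAD` of the detection
raster (default `min_snr = 6`); both statistics scale with the image, so
detection is invariant to exposure. On effectively noiseless rasters the
MAD collapses to numerical jitter from the FFT-based smoother, in which
case we fall back to the standard deviation. Peaks closer than
`min_separation` (default 2 px, chosen to keep misregistration doublets
apart) are greedily suppressed, strongest first, ties broken row-major.

Each accepted peak is refined by least squares with an elliptical 2D
Gaussian plus offset in a 9x9 window. Pixels closer to a *different*
accepted peak are excluded from the fit (a Voronoi partition), which keeps
overlapping neighbours — PTM satellites sit only ~6 px from their parent —
from inflating the fitted widths. Fits are bounded (centroid within 2 px
of the peak, widths in [0.4, 5] px); a failed fit falls back to moment
estimates and is flagged. Orientation is canonicalized to
$|\theta| \le \pi/4$ so reported widths are axis-stable.

Quantification integrates each *background-corrected* channel over the
same 3-sigma elliptical footprint (98.9% of a Gaussian's mass), so channel
ratios compare identical pixel sets. A 1-sigma "core" sum per channel is
recorded alongside: the core holds 39% of the mass and is far more
sensitive to an inter-channel spatial offset, which the classification
rules exploit.

## Ratio analysis

`log2(I_Cy5 / I_Cy3)` is computed for spots whose Cy3 **and** Cy5
intensities exceed an intensity floor (default: 3 robust sds of the
integrated background noise). Below-floor spots are excluded, not clamped:
a ratio against near-zero denominator is an artifact, not a candidate.
Per-gel distributions are summarized as box plots with whiskers at the 1st
and 99th percentiles (linear-interpolation definition); entries beyond the
whiskers are the advisory candidate cut, but the full ranking is always
emitted. Ratios are stored in log2 — symmetric in the two channels and
standard for difference gel electrophoresis — although the source
experiments plot raw ratios.

## Tracks, normalization and melting fits

Spot tables are matched across the temperature series against the
lowest-temperature (baseline) gel: an affine transform per heated gel is
estimated from mutual-nearest-neighbour pairs by least squares with one
round of 3xMAD outlier rejection, then spots are assigned greedily by
distance within `max_distance` (default 3 px). Spots absent from the
baseline start no track — without a baseline member there is no
internal-standard reference point. Fewer than 3 mutual pairs aborts to the
identity transform with a warning.

Normalization divides each channel by the Cy2 intensity on the same
footprint and then self-references each condition to its baseline value,
so both curves start at exactly 1 and per-gel gain cancels algebraically.
Whether the two conditions should instead share one reference is not
derivable from the source material; separate self-normalization was chosen
because it makes the two curves directly comparable as *fractions of the
unheated state*.

Melting fits use the logistic above, self-referenced the same way as the
data, with a coarse grid initialization ($T_m$ over the observed range,
$k \in \{0.2, 0.5, 1, 2\}$) followed by bounded Levenberg-Marquardt
(`minpack.lm::nls.lm`; the logistic is evaluated through `plogis`, which
cannot overflow, and the next-best grid starts are tried if a fit fails).
Fits require at least 4 points, a curve range above 0.2 and points on both
sides of the apparent midpoint; anything else is reported
`converged = FALSE` with missing parameters — never fabricated. Tracks
missing more than half their heated points are not fitted at all and are
flagged `partial`; they can still be screened by the longitudinal
statistic.

## Shift scoring

Two complementary statistics per track:

* **Transverse**: $\Delta T_m = T_m^{drug} - T_m^{vehicle}$ from the two
  fits, reported only when both converge.
* **Longitudinal**: `y_dev_max`, the maximum over measured temperatures of
  $|rel_{drug}(T) - rel_{vehicle}(T)|$, and `y_dev_area`, the trapezoidal
  area between the curves. Both are computed from the *data points*, not
  the fits, so a steep-slope protein whose marginal $T_m$ shift defeats
  curve fitting still registers.

`z_score` standardizes `y_dev_max` across all tracks of a run using
median and MAD, so a handful of true targets cannot inflate the scale that
judges them.

## Classification

Per track, in order:

1. **ptm_pair** — its baseline spot belongs to an opposite-colored,
   *horizontally* adjacent pair (|dy| <= 2 px, 2 px <= |dx| <= 8 px). The
   color score uses the 1-sigma cores with the floor as pseudo-intensity,
   so a Cy5-only satellite (which has no valid ratio entry) still scores
   strongly red. PTM conversion grows with treatment time in the forward
   model, and pairs vanish at zero treatment.
2. **thermal** (stabilized / destabilized) — `z_score >= 3` and
   `y_dev_max >= 0.3`, provided the baseline spot is not colored beyond
   `tau = 0.3` (a spot already red/green before heating cannot owe its
   color to a thermal shift). A baseline color *explained by* an
   equal-intensity vertical registration pair does not veto the call, but
   such tracks must additionally show transverse evidence: both fits with
   $r^2 \ge 0.85$ and $|\Delta T_m| \ge 2$ degC, because their
   longitudinal deviations are contaminated by the channel offset.
3. **registration_artifact** — member of a vertical (|dx| <= 1 px,
   |dy| <= 4 px) opposite-colored pair whose total intensities and widths
   agree within 35%, with no thermal evidence.
4. **ambiguous** — colored at baseline with no explaining partner.
5. **unchanged** — everything else.

The rules are deterministic and independent of input order, and every
track receives exactly one label.

### Calibrated operating point

The thresholds `tau = 0.3`, `min_y_dev = 0.3`, the $r^2 \ge 0.85$ gate
and `min_delta_tm = 2` degC are calibrated against the package's own
forward model at its default noise (3% signal-proportional CV plus
additive noise): inert runs must essentially never produce a thermal call
while a 2 degC shift at unit steepness (longitudinal deviation ~0.46)
remains callable. The key subtlety is that the baseline-reference
measurement error propagates into *every* point of a normalized curve, so
null longitudinal deviations are substantially larger than per-point noise
suggests; a standardized score alone would flag inert tracks regularly.
`calibrate_color_threshold()` re-derives `tau` for other noise regimes.
No multiple-testing correction is imposed beyond these thresholds — the
z-scores are reported for all tracks and the choice is stated here openly
rather than hidden.

## Dose-response

Isothermal confirmation uses a 4-parameter logistic fitted on log-dose
with a positive Hill slope and free plateaus (the response direction is
absorbed by their order). EC50 estimates inside the dosed range are
flagged `interpolated`, outside `extrapolated`; constant responses and
direction contradictions return `converged = FALSE`.

# The synthetic forward model

`generate_proteome()` + `render_gel()` emulate the statistical structure
the analysis assumes: isoelectric points uniform over the strip, log10
molecular weight uniform, log-normal abundances, melting midpoints
N(50, 5) clipped to [40, 65] degC, steepness U(0.7, 1.6) per degC,
plateaus U(0, 0.15); spots are elliptical Gaussians of width
~U(0.85, 1.15) px; per-gel log-normal gain (sd 10%), small affine warps
(translations to 2 px, linear terms to 0.5%), optional vertical Cy5
misregistration; flat background (100 counts) plus additive (sd 30) and
signal-proportional (3% CV) Gaussian noise, written as 16-bit TIFFs. PTM
substrates convert a fraction
$\varphi = \varphi_{max}(1 - e^{-t/\tau})$ of their Cy5 mass to a
satellite at pI $- 0.1$; Cy5 mass is conserved exactly between parent and
satellite. The default temperature grid is 8 points, 37-64 degC; how many
points the original experiments used is not stated, so this default is a
placeholder, not an inferred fact. Positions are rejection-sampled with a
6 px minimum spacing — *including* each species' potential satellite site —
emulating a well-resolved gel.

What the generator does **not** emulate: electrophoretic physics and
streaks, dye chemistry, detergent-dependent solubilization, saturation
blooming, non-affine warps, and Poisson shot noise (the Gaussian CV
approximation is adequate at 16-bit scale). Passing tests therefore
demonstrate correctness of the *analysis logic* under the stated
statistical assumptions, not robustness to every real-gel pathology.

`simulate_spot_tables()` produces quantified spot tables directly from the
same model (bypassing rendering); the many-replicate statistical checks —
the 100-seed inert null and melting-shift recovery — run at this level,
while the single-scenario end-to-end checks (stabilized target,
destabilized target with PTM substrates, misregistration) render and
analyze full 512x512 image series. These problem sizes (60-200 species,
256-512 px rasters, 8 temperatures, 100 seeds for statistical rates) are
the package's standard validation conditions.

# Numerical choices and degenerate inputs

* EBImage's grayscale morphology clamps to [0, 1]; rasters are rescaled by
  their maximum around every morphological call, which is exact for
  non-negative data.
* Intensities are clipped at zero after noise addition and when writing
  TIFFs (values are rounded to integer counts; the round trip is exact to
  half a count).
* Zero-variance rasters yield an empty spot table with a warning; a blank
  noise raster yields an empty table because no local maximum clears the
  robust threshold.
* `summarize_ratios()` requires >= 2 entries; `fit_dose_response()`
  requires >= 5 distinct positive doses; flat inputs return
  non-converged results, never fabricated parameters.
* All randomness flows from explicit integer seeds; per-gel streams are
  derived deterministically from the design seed, and re-running any
  pipeline with the same configuration reproduces its output tables
  byte for byte.

# Known limitations

* Low-abundance proteins fall below the intensity floor at denaturing
  temperatures and cannot be ranked there — the same detection limit the
  underlying gel method has.
* The affine registration model cannot absorb local gel distortions;
  severely warped gels would need elastic registration before matching.
* Ratio candidates are per-gel; a target whose shift is visible only as a
  subtle multi-temperature trend is found by the longitudinal statistic,
  not the single-gel ranking.
* The artifact and PTM rules are geometric heuristics with configurable
  tolerances; modifications that shift molecular weight rather than pI
  (vertical pairs with *unequal* intensities) are not explicitly modelled
  and would surface as `ambiguous`.
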