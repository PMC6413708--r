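---
title: "voltimg: models, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voltimg: models, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(voltimg)
```

This vignette is the package's account of the science it implements: the
measurement models, the assumptions behind them, how the synthetic-scene
generator was calibrated, and the numerical decisions taken where the
published procedures leave freedom. The companion README shows a worked
example; nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement problem

Wide-field imaging of membrane-localized voltage indicators is shot-noise
limited: with `n` detected photons per spatiotemporal bin, the achievable
signal-to-noise ratio of a fractional fluorescence change is
`SNR = (ΔF/F)·√n`, so a 1 % signal needs 10,000 photons for SNR 1
(`photon_budget()`). Single-AP signals from the indicator family modelled
here are ~0.1–0.6 % and negative-going, because the collected emission is
the FRET donor's, which dims as FRET efficiency rises on depolarization.
Two further constraints shape every design decision:

* **Bleaching.** Illumination bleaches the indicator at an effective rate
  proportional to intensity; usable recording time trades off against SNR.
* **Background.** Fluorescence from non-signalling structures (other
  labelled cells, out-of-focus membranes) contributes a fraction `f_b` of
  the collected light at the measured pixels, diluting ΔF/F by `(1 − f_b)`
  and SNR by `√(1 − f_b)` (the shot-noise result; the linear convention is
  selectable in `background_degradation()` and distinguishable on
  simulation, which the test suite does).

## ΔF/F₀ and bleach correction (`dff_core`)

Each pixel's time course `p_i[n]` gets an ordinary-least-squares line
`f_i[n]`; the fractional signal is
`(p_i[n] − f_i[n]) / (f_i[n] − offset)` with the camera offset (default
1600 counts) subtracted from the denominator so it counts photons, not
digitizer pedestal. Choices made here:

* **Fit frames.** Whether evoked transients should be excluded from the
  per-pixel fit is left open by the procedure's usual description;
  excluding them removes a small negative bias, so `run_pipeline()` fits
  over frames outside the stimulus windows (extended by five indicator
  time constants, `nonstim_frames()`), while `pixel_bleach_fit()` accepts
  any frame set. The fitted line is evaluated at *every* frame either way.
* **Bleach-rate map.** `−slope/(intercept − offset) × rate × 100` %/s.
  Pixels whose fitted line does not stay above the offset carry no usable
  fluorescence; they are flagged and propagate as `NA`, never silently
  zero-filled.
* **Exponential vs. linear.** The generator bleaches exponentially (the
  physical law for constant illumination); rates are nevertheless
  *measured* by linear fits, as in practice. For ≤10 s movies at ≤1 %/s
  the two differ by under 2 %, which the pipeline-recovery tests confirm.
* **Trace flattening.** `flatten_trace()` divides by a polynomial (default
  order 3) fitted only to signal-free samples, then re-expresses the trace
  as deviation from 1. For ΔF/F input (baseline ~0) the division operates
  on `1 + trace`, keeping the fit well-conditioned around 1.

## Activation maps and segmentation (`activation_segmentation`)

ΔF sequences (`p_i − f_i`, counts) are block-averaged to 50 Hz, then
either spatiotemporally Gaussian-filtered (σ = 1 frame, 1 pixel) for
display and segmentation, or 3-point median-filtered in time only for
signal-spread analysis (spatial filtering would widen the
autocorrelation). Maps are per-pixel sums over stimulus frames; active
pixels are negative under the raw convention and noise-only pixels average
to zero.

Segmentation sign-corrects the map, applies Yen's automatic threshold on a
256-bin histogram of the min–max-scaled values (a reproducible
discretization; the implementation agrees with scikit-image's
`threshold_yen` to numerical precision on frozen fixtures), performs one
round of binary closing then one of dilation with a 3×3 box (the smallest
symmetric structuring element, since only "a single round" is specified),
and keeps the largest 8-connected component; ties go to the larger summed
activation, deterministically.

One rule is the package's own: **no-detection.** A Yen threshold on a
pure-noise map always leaves a non-empty upper tail, so an explicit test
is needed to refuse returning a noise mask. Because a genuine activation
is strictly one-sided (depolarization only ever reduces donor
fluorescence) while noise is sign-symmetric, `segment_soma()` raises
"no active cell detected" when the map's positive extreme does not exceed
1.5× its negative extreme. On simulated pure-noise maps this fires in
≥95 % of seeds; on signal-bearing maps the ratio is ≳5.

## Signal metrics (`signal_metrics`)

The three amplitude rules are implemented exactly as published, on the
raw negative-going trace, returning magnitudes in %:

* long depolarization — 5th percentile during the stimulus minus the
  median of the previous 10 samples;
* first spike — extremum in the 50 ms stimulus window minus the median of
  the preceding 10 samples;
* later spikes — window extremum minus the *maximum* of the preceding
  20 ms (a conservative baseline while the previous transient decays).

The published wording mixes the plotting-inverted and raw conventions;
the package evaluates every rule on the raw trace with extrema mapped
accordingly, and keeps the deliberate first/later baseline asymmetry.
Noise is the SD of exactly the 20 samples before the stimulus. Windows in
seconds convert to frames by rounding half-up at the trace rate.

**Bleach-corrected SNR.** No formula is printed for it; the package
defaults to `SNR / √(bleach rate in %/s)`, because shot-noise SNR scales
with √intensity while the bleach rate scales linearly with intensity, so
the ratio is illumination-invariant (verified by simulation in the test
suite: 4× illumination doubles raw SNR and leaves the corrected value
unchanged within 10 %). The alternative `SNR / rate` is selectable and
every report records its convention string.

## Frame-rate analysis (`framerate_opt`)

`phase_downsample()` produces all `n` phases of block-averaged traces;
`downsample_metrics()` measures, per factor and phase, noise as the SD of
`⌊100/n⌋` signal-free points and signal as the sign-corrected stimulus
peak minus the median of the `⌊20/n⌋` preceding points; AP-timing jitter
is the spread across phases of the peak's time mapped back to the original
axis (0 at `n = 1` by construction, bounded by one downsampled frame
period). Fits are straight lines on log-log axes *versus effective frame
rate* — the orientation fixed by the signs of the published exponents
(noise exponent +0.45 ≈ +0.5, signal exponent −0.13). Per-factor values
are phase means. The `⌊100/n⌋`-point noise estimator carries real sampling
variance (exponent SD ~0.09 per trace, the same order as the published
0.45-vs-0.5 gap); property tests therefore pool seeds, while the
acceptance computation uses full-trace SDs over ≥5000 samples (exponent
spread ~0.004).

The SNR-optimal rate for `SNR(x) = (1 − A₁x^{b₁}) / (A₂x^{b₂})` has the
closed form `x* = (b₂/(A₁(b₂−b₁)))^{1/b₁}`, cross-checked against a dense
logarithmic grid search (agreement within 1 % across random parameter
draws is part of the acceptance suite).

**Aliasing model.** The indicator response to a brief depolarization is a
decaying exponential, whose power spectrum is a Lorentzian with corner
`1/(2πτ)`. `aliased_power_fraction()` reports the fraction of that power
above the Nyquist frequency — in closed form
`1 − (2/π)·arctan(π·rate·τ)`, evaluated by numerical integration with the
arctan expression as an independent oracle in the tests. The fraction
depends only on `rate·τ`; at a sampling period of `τ/2` it is 0.100,
which the package stores as its "severe aliasing" calibration point, and
inverting the rule gives `min_alias_free_rate(tau) = 2/τ` (167 Hz at
τ = 12 ms). Full-frame-period photon integration additionally attenuates
the folded components through the integrator's sinc response, so this
fraction is a conservative design metric; weighting the tail by sinc²
would lower it about tenfold and would be inconsistent with the τ/2 rule
it calibrates.

## Signal spread and crosstalk (`crosstalk`)

The spatial ACF of a *spatially unfiltered* activation map is computed as
the zero-padded full correlation of the mean-subtracted map, divided by
its zero lag, the 1-pixel central noise peak replaced by the mean of its
8 neighbours, then min–max normalized — in that order. The correlation is
evaluated via the FFT convolution theorem, which is numerically identical
to the direct sum (asserted against a direct-loop oracle in the tests).
Principal axes come from second central moments of the ≥0.5 region
(ties toward 0°); `align_average_acfs()` rotates each ACF's long axis
horizontal (bilinear interpolation, undefined corners excluded from the
average) before averaging across cells. Cutoffs are first crossings of the
interpolated axis profiles.

For neighbours at distances `r_i`, the estimated mixed-in amplitude
fraction is `1 − 1/(1 + 2·Σ ACF(r_i))`. Two things should be understood
about this formula:

* A single neighbour at the 50 % cutoff gives exactly 0.5 — the anchor
  the formula is calibrated to.
* It is a **conservative upper bound** on direct amplitude mixing. The
  package's `mixing_oracle()` measures mixing directly on two-neuron
  simulations by ground-truth attribution: the ROI-sampled
  neighbour/target brightness ratio `a` yields an oracle fraction
  `a/(1+a)`, while the formula evaluates to `2A/(1+2A)` with `A` the map
  ACF. Since `a ≤ A` for any scene of this kind (equality for a uniform
  extended structure; `a < A` when a bright soma dominates the map), the
  formula exceeds the oracle by a factor between about 1.3 and 2.5
  depending on geometry — visible already at co-location, where symmetry
  forces the oracle to 0.5 while the formula gives 2/3. Users planning
  expression sparsity with `plan_sparsity()` therefore get distances that
  are safe rather than exact.

Hexagonal-grid enumeration truncates at 3× the lattice spacing by default
(the ACF is below its noise floor beyond that in the regimes measured
here); best/worst cases read the short/long axis respectively.

## The synthetic scene generator and its calibration

The generator exists so every stage can be validated against ground
truth. It emulates: membrane-localized fluorescence (projected spherical
shells — a bright annulus with a dimmer interior lit by top/bottom
membrane — plus projected-cylinder dendrites, Gaussian defocus);
negative-going ΔF/F with single-exponential kinetics (`τ` configurable;
0.02 s at room temperature in the preset, 0.012 s at 34 °C for the
500 Hz analyses); frame integration by ≥10× supersampling and averaging
within each frame period; single-exponential bleaching applied to neurons
*and* background (the background is other cells' indicator under the same
illumination — without this the per-pixel rate map is diluted); a uniform
background contributing fraction `f_b` of total collected fluorescence;
Poisson shot noise (variance = expected photons, verified) and Gaussian
read noise; full determinism given the seed, with trial `k` using
`seed + k`.

**Calibration of `scene_table1()`.** The preset's job is to land the
*measured* pipeline outputs at the magnitudes of the published 100 Hz
sparse-line recordings (4-trial averages): AP signal ~0.14 %, 100 ms
depolarization ~0.59 %, baseline noise 0.04–0.07 %, bleach 0.52 %/s.
Frozen values: 96×96 px at 1.04 µm, soma radius 11 µm (a normal cortical
pyramidal soma), membrane 3 µm, defocus 0.8 µm for the patched cell and
2.5 µm for the off-focus neighbour, 6000 photons per soma-membrane pixel
per frame, `f_b = 0.75`, bleach 0.52 %/s, and configured amplitudes
carrying a 1/0.71 factor because ambient fluorescence dilutes the
ROI-measured amplitude by ×0.71 in this scene. Two calibration lessons
are worth recording. First, amplitudes are membrane-true quantities; what
Table-like summaries report are ROI measurements after dilution, so the
preset must compensate. Second, the high background fraction is not
cosmetic: Yen's threshold sits a few standard deviations above the
*background* noise floor, while an inactive neighbour's membrane pixels
fluctuate with their own (much larger) photon count. Only when ambient
background supplies a comparable per-pixel photon flux — as it does in
tissue — does the neighbour stay below threshold, reproducing activity
maps in which only the stimulated cell appears. With unrealistically
clean backgrounds the neighbour's shot noise prints through.

What passing tests on this preset do show: the pipeline recovers
segmentation (IoU vs. the true soma footprint ≥ 0.6), amplitudes, noise
and bleach rates within the published envelopes, and activation maps
overlap the active cell's anatomy (Dice ≥ 0.5) but not the inactive
neighbour's (≤ 0.05), with medians over three simulated cells, mirroring
how such studies report medians over cells. What they do not show:
performance on real tissue with scattering, motion, heterogeneous
expression, dendritic filtering, or correlated physiological noise — none
of which the generator models (defocus blur is its only optical effect).

## Problem sizes and runtimes

Validation runs use desk-scale sizes chosen to keep the full suite under
a minute on one core while leaving every estimator in its operating
regime: 96×96 px × 320-frame preset movies × 4 trials × 3 seeds for
pipeline recovery; 400×100 px two-neuron scenes at 5 separations × 3
seeds for the mixing comparison; 6000-sample 500 Hz traces for the
downsampling analyses; 100 random parameter draws for the optimal-rate
cross-check.

## Known limitations

* The optical model is projection + Gaussian defocus; no scattering or
  depth-dependent PSF, so deep-tissue broadening is out of scope.
* AP waveforms are stereotyped templates; there is no membrane-potential
  biophysics, and ephys traces are companions for display and alignment,
  not simulations of excitability.
* The ACF crosstalk formula deliberately over-estimates direct amplitude
  mixing (see above); treat its output as a bound.
* One somatic ROI per activation map, by construction of the
  largest-component rule; joint demixing of overlapping cells is not
  attempted.
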