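---
title: "Inferring paleoclimate from fossil tree rings and paleosols: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring paleoclimate from fossil tree rings and paleosols: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodendro)
```

## The problem

Annually resolved meteorological records do not exist for deep time, and the
trees that grew at high paleolatitudes are extinct, with no modern analogue to
calibrate against. What fossil wood does preserve is the *relative* year-to-
year variation of ring widths. Because climate is among the strongest state
factors of tree growth — especially for trees at the limit of their range —
that variation encodes the oscillatory structure of the climate the trees
lived through. This package implements the full chain from raw ring-width
measurements (and, independently, paleosol major-element chemistry) to
paleoclimate inference:

1. **cross-dating** floating ring-width series into a common chronology,
2. **detrending** to a ring-width index (RWI) and assessing chronology quality,
3. **wavelet analysis** of the RWI against a red-noise null,
4. a **growth–climate coincidence statistic** tying significant oscillations
   to suppressed or enhanced growth, and
5. a **paleosol proxy chain** giving an independent climate estimate from the
   same landscapes.

A synthetic-data generator reproduces the statistical structure this chain
assumes, so every stage is testable end to end without any field data.

## Cross-dating

Two series are compared at every lag with at least `min_overlap` common years
(default 20 — fewer rings make replicable cross-dating unreliable). At each
lag we compute:

* `t_BP`: Student t of the Pearson correlation of the Baillie–Pilcher
  transform, `ln(width / 5-yr centered moving average)` — a high-pass index
  that removes growth trend and scale;
* `t_HO`: the same for the Hollstein transform, `100 log10(w_t / w_{t-1})`,
  the year-on-year growth ratio;
* `r`: the Pearson correlation of the Baillie–Pilcher indices;
* `GLK` (Gleichläufigkeit): the percentage of year-to-year changes with equal
  sign (ties between a flat and a moving interval score 0.5; two flat
  intervals score 1).

A lag is *accepted* when `t_BP >= t_min`, `t_HO >= t_min`, `r >= r_min` and
`GLK >= glk_min` (defaults 3.5 / 0.5 / 65%; all config-exposed). Both
t-statistics must pass: an exhaustive scan evaluates on the order of a
hundred lags, and a single `t >= 3.5` at a minimal 20-year overlap is
reachable by chance often enough that, gating on `t_BP` alone, independent
red-noise pairs were accepted in ~11% of Monte-Carlo replicates. With the
joint gate the measured false-positive rate is below 5% (see
`test-crossdating.R`).

Replicate radii of a tree are cross-matched and averaged (arithmetic mean per
year) before inter-tree matching; radii that fail to match are dropped and
reported. Accepted matches form a graph whose edges carry lags; offsets are
composed along the graph, cycles whose lags do not sum to zero raise an
alignment-conflict error, and series disconnected from the first series'
component are excluded (real assemblies lose the occasional sample the same
way). The chronology length is the span of the union of aligned years.

## Detrending and chronology statistics

The age trend is removed with a discrete penalized smoothing spline
(second-difference penalty). Its transfer function is exactly
`1 / (1 + lambda (2 - 2 cos w)^2)`, which gives a closed-form map from the
wavelength at which the response is 0.5 to the penalty `lambda`. The default
cutoff is 0.67 of the series length — the dominant dendrochronological
convention, stiff enough to keep multidecadal climate signal in the index.
`RWI_t = width_t / fitted_t`, so 1 is "expected growth", below 1 suppressed,
above 1 enhanced; fitted values are floored at a small epsilon so the index
is always defined.

Series are averaged per year with a Tukey biweight robust mean (c = 9),
falling back to the arithmetic mean when fewer than four series contribute.
Chronology quality is summarized by `rbar` (mean pairwise correlation of the
RWIs over each pair's common years, pairs with ≥ 10 common years) and the
subsample signal strength

`SSS(n) = n (1 + (N-1) rbar) / (N (1 + (n-1) rbar))`,

evaluated with the per-year sample depth `n`. The usable part of a chronology
is taken to start where SSS reaches 0.5 — a deliberately permissive
convention (0.85 is common in neo-dendrochronology), exposed as
`sss_cutoff`. A Shapiro–Wilk diagnostic with probability-plot quantiles is
reported before wavelet analysis; it is advisory, since the χ² significance
of wavelet power assumes Gaussian input.

## Wavelet analysis

`cwt()` is an FFT implementation of the continuous wavelet transform on a
dyadic scale grid `s_j = s0 * 2^(j dj)` with `dj = 1/16` (16 voices per
octave) and `s0 = 2` years, extended until the largest Fourier period equals
the series length. The input is mean-removed and variance-normalized, so
power is in units of the series variance. Two wavelets are provided:

* **Morlet** (ω₀ = 6): complex, best frequency resolution; Fourier period
  `4 pi s / (w0 + sqrt(2 + w0^2)) ≈ 1.03 s`. We use the exact admissible
  (zero-mean) Morlet — including the `e^{-w0^2/2}` correction term and its
  full spectrum rather than a positive-frequency truncation. For ω₀ = 6 the
  difference from the truncated plane-wave form is below 1.5 × 10⁻⁸, but the
  exact form makes the frequency-domain filter the exact Fourier transform of
  the time-domain wavelet, so the FFT path and a direct convolution agree to
  numerical precision (the equivalence test requires 10⁻⁸ at every cell).
* **DOG(2)** (Mexican hat): real and antisymmetric-free, so coefficients are
  time-aligned and directly comparable to the RWI year by year; Fourier
  period `2 pi s / sqrt(2.5) ≈ 3.97 s`.

The oracle-equivalence test runs at `s0 = 4` years: below ~4 sampling
intervals the discretized Morlet kernel is genuinely undersampled, and the
FFT filter (spectrum truncated at Nyquist) and a sampled time-domain kernel
(spectrum aliased) are *different* discretizations of the same operator.
Analyses keep `s0 = 2`, where the transform itself is standard practice; the
comparison is only meaningful where both discretizations are faithful.

The cone of influence is the e-folding period `sqrt(2) s` mapped to Fourier
period, growing linearly from both edges; zero-padding to the next power of
two confines wrap-around artefacts outside it. A Parseval-style identity
(rectified power summing to the variance within 10%) holds for the cyclic
(unpadded) transform; padding deliberately sheds edge power — that loss is
exactly what the COI quantifies.

**Red-noise significance.** The null is an AR(1) process with lag-1
coefficient α (estimated from the series or supplied). The theoretical test
compares each cell's power with
`P(f) = (1 - a^2) / (1 + a^2 - 2 a cos 2 pi f)` times `chi²_nu(0.95)/nu`,
with ν = 2 for the complex Morlet and ν = 1 for the real DOG. A Monte-Carlo
alternative pools in-COI power of AR(1) surrogates per scale and takes the
(1 − level) quantile; fewer than 100 surrogates records a warning. Calibration
is checked by simulation: on pure AR(1) input (φ = 0, 0.4, 0.7; 500 series of
200 years each) the theoretical test flags 5% ± 2 percentage points of
in-COI cells.

**Cross-wavelet and coherence.** `xwt()` gives `W_XY = W_X conj(W_Y)`; its
phase encodes the sign of the local correlation (0 in phase, π antiphase,
±π/2 a quarter-period lead/lag). Squared coherence smooths `W_XY / s` with a
Gaussian in time (standard deviation equal to the scale) and a 0.6-octave
boxcar in scale before normalizing — unsmoothed coherence is identically 1,
so disabling smoothing is an error. Significance is Monte-Carlo over AR(1)
surrogate *pairs* matching the two series' α estimates: per-scale cell
thresholds from pooled in-COI coherence, and a per-period test of the
COI-interior mean coherence against the surrogate (1 − level) quantile.
`wavelet_coherence()` takes the two raw series (rather than spectra) because
the surrogate path must recompute transforms internally anyway; coherence is
thereby always Morlet-based — the smoothing kernel is not defined for DOG
spectra.

## The growth–climate coincidence statistic

`growth_response()` marks a chronology year *significant* when any DOG(2)
cell with Fourier period inside the band (default 20–40 yr, bracketing
multidecadal oscillations near 30 yr) passes red-noise significance at that
year while inside the COI. Significant years are then classified by their
RWI: suppressed (< 1), enhanced (> 1), neutral (exactly 1, excluded from both
numerator classes). The statistic depends only on the significance mask, not
on the power magnitudes. `contrast_epochs()` differences the suppressed
fractions of two epochs with a seeded bootstrap CI over significant years.

A subtlety governs what this statistic *can* recover. For a purely
sinusoidal climate signal coupled multiplicatively into growth, the
suppressed/enhanced split of significant years is provably blind to the sign
of the coupling: `exp(g C)` and `exp(-g C)` are the same waveform shifted by
half a period. Sign recovery requires a *skewed* oscillation — once the
waveform has sharp extremes on one side (here built from a phase-aligned
first harmonic: periods 30 and 15 yr, amplitudes 1 and 0.5), adverse coupling
turns the sharp phase into deep narrow rings whose localized, broadband
wavelet response dominates the in-band significance mask, and the suppressed
fraction rises above 50%; favorable coupling mirrors it below 50%. Real
multidecadal climate modes are skewed in exactly this sense, and trees
respond more sharply to adverse than to favorable years. The recovery test
(100 seeds per sign, six trees × two radii × 238 yr, gain ±0.8, AR(1) 0.3)
requires the correct majority in at least 90 seeds of each arm.

## The synthetic generator

`simulate_forest()` draws widths from

`w(t) = max(floor, w0 e^{-decay a}) * exp(g C(t) + eps(t)) * m(t)`

with ring age `a`, shared climate `C(t)`, per-radius AR(1) noise `eps` (burn-in
50 steps, innovations scaled so `noise_sd` is the marginal SD), and shared
multiplicative marker years `m(t)` applied after noise — widths are strictly
positive and right-skewed, as measured ring widths are. `C(t)` is a sum of
(optionally interval-gated, hence non-stationary) sinusoids *plus a shared
interannual white component* (`climate_noise_sd`, default 0.8). The white
component is essential, not cosmetic: with a purely sinusoidal common signal,
alignment is ambiguous — shifts that re-phase the short-period components
score nearly as well as the truth — whereas shared year-to-year weather is
precisely the signal cross-dating exploits. The default of 0.8 (with
`signal_gain` 0.5 and `noise_sd` 0.3) puts transformed inter-series
correlations in the 0.7–0.8 range such chronologies exhibit.

Each radius draws from its own stream seeded by
`(seed + 7919 * index) mod (2^31 - 1)` (the shared climate uses index 0), so
output is reproducible per series and byte-identical per seed. `years` is the
ring count per tree; with per-tree start-year `offsets` the true chronology
span, offsets and climate are returned as recoverable metadata.

What the generator does **not** emulate: missing and false rings, within-ring
anatomy, heteroscedastic measurement error, taphonomic loss of the juvenile
core, age-dependent signal strength, and disturbance pulses (fire, insects)
uncorrelated with climate. Passing tests therefore demonstrate the statistical
machinery under the model's own assumptions — they do not show that the
assumptions hold for any particular fossil assemblage.

`simulate_paleosol()` builds a horizon profile by scaling the parent's Ca and
Na down by the exact factor that raises CIA-K by the requested per-horizon
increment (so the weathering gradient is exact before noise), with mild
authigenic K and Mg enrichment and Mn depletion in the B horizons, plus
additive measurement noise (default 0.1 wt%).

## Paleosol proxies

Weight percents are converted to moles with the standard oxide molar masses.
With molar quantities and CaO* the silicate-bound Ca (default CaO* = CaO for
carbonate-free profiles; a McLennan-style cap `min(CaO, Na2O)` is available):

* `CIA = 100 Al / (Al + Ca* + Na + K)`; `CIA-K = 100 Al / (Al + Ca* + Na)`;
* authigenic-K correction: with `m = K / (Al + Ca* + Na + K)` of the parent,
  `K_corr = m (Al + Ca* + Na) / (1 - m)` — idempotent, with parent-proportion
  K as its fixed point;
* `MAP = 221.1 exp(0.0197 CIA-K)` mm/yr (standard published calibration);
* `LST = 0.56 CIA_corrected - 25.7` °C — shipped as a **provisional**
  default, to be overridden with a calibration appropriate to the
  soil-forming setting (`strict = TRUE` refuses defaults);
* `Eppt = MAP × c_p × (LST - T_ref)` and a temperature-based annual
  potential-evapotranspiration stand-in for ET, both in MJ m⁻² yr⁻¹ — these
  and the humidity-province boundary polylines are labelled synthetic
  placeholders with the right qualitative behaviour, all config-replaceable.
  Classification is total over the (ET, Eppt) plane; points on a boundary go
  to the wetter province.

Profile QC follows the rule that pedogenesis is considered preserved when the
mean B-horizon CIA-K differs from the parent CIA-K by more than 5%.

## Numerical and design choices

* Spline cutoff fraction 0.67, BP window 5 yr, `min_overlap` 20 yr,
  acceptance gates 3.5 / 65% / 0.5 — all config-exposed; the method sources
  cite the procedures without fixing every constant, so the package ships the
  field's standard values.
* Degenerate inputs: constant series give exactly zero wavelet power (not an
  error); perfect correlations are reported as degenerate with `t = Inf`
  sentinels; zero-variance overlaps are flagged, never crash the scan.
* `years` per tree ≥ 20 and `ar1_phi ∈ [0, 1)` are enforced at config time;
  all width parameters must be finite and positive.
* Tie-breaks in the lag ranking: higher GLK, then smaller |lag|, making
  results deterministic.
* Problem sizes in the test-suite simulations (500 × 200-yr series for
  significance calibration, 100-seed recovery experiments, 300 surrogate
  pairs for coherence) were chosen so the whole suite completes in a few
  minutes while keeping Monte-Carlo error comfortably inside the asserted
  margins.

## Known limitations

* Calendar anchoring and dating against reference master chronologies are out
  of scope: all year axes are chronology-internal ("floating").
* SSS uses the whole-chronology `rbar`; running-window `rbar` is not
  implemented.
* No regional-curve standardization, variance stabilization, or
  autoregressive prewhitening of chronologies.
* The theoretical χ² significance assumes approximately Gaussian input; the
  normality diagnostic warns but does not block.
* The LST, Eppt/ET transfers and humidity-province boundaries are stand-ins
  pending setting-specific calibrations; conclusions should not rest on their
  absolute values, only on contrasts computed with a consistent configuration.
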