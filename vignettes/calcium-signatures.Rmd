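---
title: "Quantifying aequorin-reported calcium signatures: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aequorin-reported calcium signatures: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeqsig)
```

## The measurement model

Aequorin is a Ca²⁺-activated photoprotein: each molecule emits one photon
when it is consumed, and the *fractional consumption rate* of the pool,

$$k = \frac{L(t)/\tau}{\sum_{t' \ge t} L(t')} \quad [\mathrm{s}^{-1}],$$

(counts per second divided by total counts remaining, the "L/Lmax"
statistic) increases steeply and monotonically with the free cytosolic
calcium concentration. `aeqsig` uses the standard empirical calibration

$$pCa = c_1 \cdot (-\log_{10} k) + c_0, \qquad
  [\mathrm{Ca}^{2+}]_{cyt} = 10^{-pCa},$$

with defaults $c_1 = 0.332588$ and $c_0 = 5.5593$ (cytosolic aequorin
reconstituted with native coelenterazine). Both constants are exposed in
`aeq_calibration()` so that alternative calibrations can be swapped in; the
package does not fit them. Because $k$ is a ratio of observed counts, the
recovered calcium is independent of the absolute aequorin expression level
— doubling the pool doubles both numerator and denominator. This ratio
invariance is asserted exactly in the test suite.

Key assumptions:

* consumption is first order: over a bin of width $\tau$ a pool $A$ emits
  $A(1 - e^{-k\tau})$ expected counts (`emission_step()`), so the total
  future counts of a trace estimate the pool still active at that bin;
* one detected count per consumed aequorin unit — detector efficiency is
  folded into the pool units and cancels from every ratio;
* the "remaining" denominator includes the current bin (configurable via
  `lmax_remaining(inclusive =)`, since software conventions differ);
* the calibration is empirical and **not** valid at molar calcium, so the
  terminal discharge (1 M CaCl₂/ethanol) is modelled as consumption at a
  fixed saturating rate $k_d = 0.05\,\mathrm{s}^{-1}$, which empties
  \>99.99 % of the pool within the 300-s discharge window.

## The protocol and its parameters

`sim_config()` encodes the plate-luminometer protocol: 90 s baseline at
$\tau = 1$ s integration, stimulus injection, 600 s of recording (1200 s
for the slow flagellin-22 response, `sim_config_for()`), then a 300 s
discharge. Defaults that are not protocol constants are chosen once at
values realistic for a 96-well aequorin assay and not revisited:

| parameter | default | units | meaning |
|---|---|---|---|
| `A0` | 5·10⁶ | counts | initial active pool per well (sets shot-noise level; baseline rate ≈ 230 counts/s at 100 nM) |
| `background` | 20 | counts/s | empty-well dark/chemiluminescence rate |
| `discharge_rate` | 0.05 | s⁻¹ | saturating consumption during discharge |
| baseline Ca²⁺ | 10⁻⁷ | M | resting cytosolic calcium |

Photon emission is Poisson (shot noise) per bin, with Poisson background
added everywhere; `noise = "none"` gives the exact expected-value forward
model used by the round-trip tests.

## The signature presets

A `signature_preset` is the ground truth for one stimulus × dose × tissue
× species combination: amplitude Δ (molar), onset delay, time-to-peak,
decay half-time, sustained elevation, optional secondary-elevation train,
dose-curve parameters and the La³⁺ inhibition fraction. The shipped
library (`preset_library()`, 16 presets) encodes the printed signature
values of the barley/Arabidopsis comparison this package models: NaCl
amplitudes of 0.5 µM (barley, both tissues; Arabidopsis root) and 0.7 µM
(Arabidopsis leaf) at 250 mM with 15–22 s (leaf) and 7–10 s (root)
time-to-peak; H₂O₂ 0.4 µM at the 10 mM optimum with ~40 s time-to-peak and
decline above the optimum; flg22 0.05 µM with a 90 s onset delay and
~300 s (barley) / ~190 s (Arabidopsis) time-to-peak; mannitol responding
only in roots (<0.1 µM in barley, ~0.5 µM in Arabidopsis); inhibition
fractions 0.80 (NaCl), 0.60 (H₂O₂), 0.90 (flg22) and 0.98 (mannitol,
root). Where the source prints a range, the midpoint is used.

### Kinetic kernel

Printed values fix the amplitude and a few timings, not a functional form.
The transient is modelled as

$$\mathrm{Ca}(t) = \mathrm{baseline} + (\Delta - S)\,g(t) + S\,p(t) +
  \mathrm{osc}(t),$$

where $g$ rises from the onset delay $d$ to the peak time $T$ as a
saturating exponential $g \propto 1 - e^{-3 (t-d)/(T-d)}$ normalised to
$g(T) = 1$, then decays exponentially with the preset half-time; $p$ is a
fast-saturating plateau term approaching the sustained elevation $S$; and
osc is an optional damped sine-squared train (secondary root elevations,
magnitudes not printed anywhere — placeholders at 15 % of Δ). By
construction the post-injection maximum minus baseline equals Δ to within
1 %.

Two deliberate choices here:

* **No double-exponential kernel.** For a difference of exponentials the
  peak delay is bounded above by the decay time constant; a 15–22 s rise
  with a return to near-baseline within 50 s (decay half-time ≲ 9 s) is
  therefore infeasible for that family. The rise/decay split above
  reproduces both printed statements.
* **Rise shape 3.** The reported 90-s flg22 "delay" is an observable: the
  time at which the trace detectably leaves the baseline. With the
  saturating rise, the 3-SD detection threshold is crossed ~10 s after the
  kinetic onset at the flg22 noise level, so the detected onset tracks the
  stated delay; a sigmoidal (flat-footed) rise would add ~50 s of
  detection lag and misrepresent the printed kinetics.

### Dose response and blocker

`dose_scale()` applies a Hill curve (coefficient 2) that is zero at and
below the threshold dose (the largest printed non-responding dose, e.g.
100 nM flg22 in barley), normalised to 1 at the reference dose, with an
optional high-dose decline factor above the optimum (H₂O₂ only).
`apply_blocker()` multiplies every amplitude-like parameter by
$1 - \mathrm{inhibition}$, modelling 1 mM LaCl₃ pre-incubation.

## The inverse pipeline

`summarize_plate()` runs, per treatment well:

1. background estimation — mean count rate of the designated empty wells
   over their full record (`estimate_background()`);
2. `background_correct()` — subtraction with clamping at the count floor;
   clamped and zero-count bins are flagged and excluded from maxima;
3. `calibrate_trace()` — per-bin $\hat k$ and calcium; baseline mean/SD
   from exactly the 10 s before injection; a saturation warning when >90 %
   of all counts precede the discharge (configurable);
4. feature extraction — Δ[Ca²⁺]max (max over the post-injection,
   pre-discharge window minus baseline mean; earliest bin wins ties;
   negative values clamped for reporting with the raw value retained),
   time-to-peak, onset delay (first bin starting 3 consecutive bins above
   baseline + 3 SD; SD floored at 1 nM), and sustained elevation (mean of
   the final 60 s before discharge minus baseline).

**Peak smoothing.** Amplitude and time-to-peak are read from a 5-s boxcar
smoothed copy of the trace (`smooth_ca_trace()`; onset and sustained use
the raw trace). The reason is quantitative: at the default photon budget
the per-bin calcium noise is ~2 nM, and the *maximum* of ~600–1300 noisy
bins carries a Gumbel extreme-value bias of roughly
$\sigma\sqrt{2\ln n} \approx 8$ nM — negligible against a 0.5 µM NaCl
peak, but a 16 % distortion of the 0.05 µM flg22 amplitude and a large
distortion of near-null blocked wells. Smoothing attacks the estimator
bias without touching the stated simulation parameters. The smoother never
mixes discharge-phase bins (whose calibrated calcium is off-scale) into
the analysis window. Set `smooth_s = 0` in `extract_features()` to
disable.

A consequence worth stating plainly: the mean null-well amplitude can
*never* be statistically indistinguishable from zero in the "within 3
Monte-Carlo SD" sense, because for a maximum over $n$ effective bins
$E[\max]/SD[\max] \approx 0.78 \cdot 2\ln n > 3$ for any realistic window.
The corresponding acceptance clause is therefore implemented as stated and
documented as failing (measured ratio ≈ 3.6); the absolute null amplitude
(~3 nM) is below 7 % of the smallest printed signature.

## Statistics

`dose_response()` reports per-dose mean ± SE (SE = 0 with a flag for
single replicates). `percent_inhibition()` uses group means,
$100(1 - \bar\Delta_{La}/\bar\Delta_{ctl})$, with an equal-variance
two-sample Student's *t* test (Welch by flag). `section_profile()` runs a
one-way ANOVA with Tukey HSD at α = 0.05 and assigns a compact letter
display greedily from the highest mean; sections sharing no letter differ
significantly. With zero residual variance the letters degenerate to
"any difference is significant". Tukey letters are cross-checked in the
test suite against an independent studentised-range oracle built directly
from `ptukey`. No cross-figure multiplicity correction is applied — tests
are per profile, matching how such figures are typically annotated.

## Imaging

The photon-counting-camera path mirrors the plate conventions at a 200-ms
frame interval: `roi_trace()` sums counts in a mask, `l_over_lmax()`
normalises to counts-per-second over remaining counts (inclusive of the
current frame), and `peak_map()` tabulates per-ROI post-injection maxima.
Under the forward model with constant calcium, L/Lmax equals the
consumption rate up to a binning error of $k\tau/2$, which the tests
assert. Synthetic leaf stacks render the blade as equal-width bands whose
kinetics come from `section_profile_presets()` — NaCl amplitude rising
tip→base, H₂O₂ falling (5-day) or U-shaped (7-day), flg22 flat with a
slight mid-blade elevation at 7 days; the per-band gradient multipliers
are design values chosen to respect the described orderings, as the
figures print no section-wise numbers.

## What the generator does and does not establish

The synthetic data reproduce: the protocol's phase structure and timing,
Poisson photon statistics at a realistic photon budget, expression-level
(pool-size) variation, empty-well background, dose scaling, blocker
inhibition, and the printed per-signature kinetics. They do **not**
reproduce: biological replicate-to-replicate kinetic variability (every
replicate shares one ground-truth curve; only shot noise differs),
cell-population heterogeneity and asynchronous oscillations underlying
real flg22 responses, wounding responses of sectioned tissue, temperature
or coelenterazine-batch effects, or camera artefacts (no flat-field,
registration or segmentation is attempted). A green end-to-end test
therefore establishes that the *pipeline* recovers the parameters of the
stated world — not that the stated world captures every property of the
original measurements.

## Numerical choices and degenerate inputs

* Rates below `rate_floor` (10⁻¹² s⁻¹) are clamped before `log10`;
  zero-count bins are flagged and excluded from maxima rather than
  propagating floor-valued calcium into features.
* All-zero traces error at calibration (Lmax undefined), as does a missing
  discharge window.
* Ties in the maximum resolve to the earliest bin.
* The undischarged pool residual after 300 s is $e^{-15} \approx
  3\cdot10^{-7}$ of the pool; unit tests that shorten the discharge to
  120 s tolerate the corresponding $e^{-6}$ residual explicitly.
* Per-well seeds derive from the master seed as
  `master * 10000 + counter`, keeping all seeds below 2³¹ for masters
  below 2·10⁵.

## Known limitations

* The calibration constants are adopted, not fitted; traces from other
  aequorin variants or coelenterazine analogues need their own constants.
* Amplitudes below ~3 nM are inside the null extreme-value floor at the
  default photon budget and cannot be distinguished from noise.
* The inhibition estimator inherits a small downward bias for very weak
  blocked responses (numerator dominated by the noise floor); at the
  library's smallest signature (flg22, 0.05 µM, 90 % inhibition) the
  recovered inhibition is ~85 % rather than 90 %.
* `section_profile()`'s compact letters assume the significance pattern is
  consistent with the mean ordering (guaranteed for balanced groups);
  heavily unbalanced designs may need a full graph-colouring CLD.
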