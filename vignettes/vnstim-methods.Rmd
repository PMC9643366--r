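---
title: "Methods: spike-train regularity, GVS dosimetry and receptor dose-response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train regularity, GVS dosimetry and receptor dose-response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnstim)
```

vnstim re-implements, as a tested pipeline over synthetic data, the analysis
of vestibular-nucleus (VN) single-unit electrophysiology and glutamate-receptor
histology in a 6-OHDA Parkinson's-disease (PD) rat model under galvanic
vestibular stimulation (GVS). This vignette is the package's account of the
underlying models, the tunable parameters, and the design choices that were
genuinely open.

## The discharge-regularity model

Vestibular neurons are classically split into regular and irregular
dischargers. The raw coefficient of variation of inter-spike intervals (ISIs),
$CV = \sigma_{ISI}/\mu_{ISI}$, confounds regularity with firing rate, so the
analysis uses a rate-normalized statistic,

$$
CV^{*} \;=\; 10 \times
\left[\frac{CV}{0.7116\,\log_{10}(\mu) - 0.8248}\right]
^{1/(0.00002\mu^{3} - 0.0024\mu^{2} + 0.0731\mu + 0.37)},
$$

with $\mu$ the mean ISI **in milliseconds**. Two conventions in this formula
are not self-evident and are handled as follows:

* **Logarithm base.** The normalization coefficients are of the magnitude used
  with base-10 logarithms in the vestibular-afferent regularity literature, so
  `log10` is the default; `cv_star(..., log_base = "ln")` is available and the
  choice is echoed into every pipeline manifest.
* **Units of $\mu$.** The cubic in the exponent only produces sane exponents
  for $\mu$ of order 10–100, which matches milliseconds at resting rates of
  14–34 spk/s; $\mu$ in seconds would put the exponent at $1/0.37$ for every
  unit. Milliseconds are therefore fixed, not switchable.

The normalizing denominator $0.7116\log_{10}\mu - 0.8248$ has a root at
$\mu \approx 14.42$ ms. Below it the bracket is negative or divergent, so
`cv_star()` raises an error there and `classify_regularity()` labels such
units `"unclassifiable"` rather than silently defaulting. The implementation
is checked against a 50-digit arbitrary-precision evaluation of the formula on
a 20-point $(\mu, CV)$ grid to 10 significant digits.

### The regular/irregular threshold

No cutoff value is inherent to $CV^*$. The package's default is calibrated by
simulation: score the resting $CV^*$ of a regular reference population
(gamma renewal, $CV = 0.1$) and an irregular one ($CV = 1.0$), both at
$\mu = 30$ ms, and take the geometric midpoint of the two median $CV^*$
values. `calibrate_regularity_threshold()` reproduces this; the frozen default
is `r default_regularity_threshold()` (the analytic log-midpoint of the
population values, $\sqrt{4.206 \times 48.337} \approx 14.26$, agrees). The
two reference populations sit roughly a decade apart on the $CV^*$ scale
(about 4.2 versus 48), so classification is insensitive to the exact midpoint;
the threshold is user-overridable everywhere and recorded in every output.

## The synthetic spike-train generator

No recordings are available, so every downstream stage is driven by a
generator whose defaults are the study conditions:

* **Resting discharge** is a gamma renewal process with shape $k = 1/CV^2$ and
  mean `mean_isi`. The gamma family is the standard regular-to-irregular
  continuum: $CV \to 0$ recovers a pacemaker, $CV = 1$ recovers a Poisson
  process, and $CV$ can be dialed exactly. $CV = 0$ produces a deterministic
  periodic train (supported at rest only).
* **Modulated epochs** (sinusoidal rotation/translation, GVS steps) are
  inhomogeneous renewal processes built by time rescaling: a unit-mean gamma
  renewal sequence is generated on the axis of the integrated rate
  $\Lambda(t) = \int r(s)\,ds$ and mapped back through $\Lambda^{-1}$
  (numerically, trapezoidal $\Lambda$ on a 1 ms grid with monotone linear
  inverse interpolation). The local rate then follows the target profile while
  interval dispersion retains the unit's $CV$. Rate functions that would go
  negative are rejected (`invalid modulation`).
* **Phasic GVS adaptation** is a single-exponential decay from the step peak
  (`baseline + amplitude`) toward a plateau (default: back to baseline). The
  emulated study reports only endpoint rates for its phasic example
  (66.1 decaying to 36.2 spk/s), so the time constant is a free parameter
  (default 4 s against a 16 s epoch).

The default cohort reproduces the study census: 65 units, 32 canal (20 from
non-lesioned animals) and 33 otolith (21 non-lesioned), resting rates drawn
uniformly from 14–34 spk/s for normal and PD alike (the study found no
significant resting-rate difference, so the generator is null by default).
The regular/irregular and tonic/phasic splits are 50/50 within each cell —
the study does not report those counts. Head-motion stimulus parameters are
not reported either; the defaults (0.5 Hz, relative amplitude 0.8) are
placeholders a user is expected to override, and only relative quantities are
asserted about them in tests.

**What the generator does not emulate.** Real afferents are refractory; a
pure renewal process is not. One visible consequence: for $CV = 1$ the
expectation of the reciprocal ISI diverges, so the windowed mean IFR of
simulated irregular units is heavy-tailed and can sit far above the 14–34
spk/s band of mean *rates*. Group contrasts on those values remain
null-calibrated (both conditions share the distribution), but absolute mean
IFR magnitudes for irregular units should not be read as physiological.
Passing tests therefore demonstrate statistical correctness of the pipeline,
not biological realism of extreme-interval behavior.

## Response characterization

The instantaneous firing rate (IFR) is the reciprocal of each ISI,
timestamped at the second spike of its interval (causal convention — a rate is
known only once its interval completes; this affects only windowed averages).
The resting rate is the arithmetic mean of IFR values in the first 10 s of the
resting epoch (offset configurable). Epoch-boundary-straddling intervals are
excluded, not truncated.

* **Kinetic responses.** Peak and trough are extremes of a moving-median
  smooth of the epoch IFR (default width 5 intervals; raw reciprocal ISIs are
  heavy-tailed). The modulation depth is the larger excursion from the resting
  rate. The study's "kinetic responding gain" is reported without a stimulus
  amplitude to normalize by, so depth in spk/s is the primary measure;
  supplying `stimulus_amplitude` additionally reports depth/amplitude. The
  extreme-value bias of the smoothed maximum grows with interval $CV$ (about
  +40% at $CV = 0.3$ for a 20 s epoch), which is a property of this standard
  estimator, not of the generator; peak-recovery checks are run at the
  regular-unit $CV$.
* **Tonic versus phasic GVS.** The study classifies only qualitatively. The
  package operationalizes it with an adaptation index
  $AI = (R_{early} - R_{late})/\max(R_{early}, R_{late})$, the mean IFR of
  the first versus last quarter of the GVS epoch. $AI$ is dimensionless and
  invariant to time translation and uniform rate scaling. $|AI| > 0.25$
  (configurable, always recorded) is classified phasic. Quarter-based
  averaging means the index under-reads the peak-to-plateau drop when the
  decay is fast relative to the epoch; with the default $\tau$ equal to the
  epoch quarter, a 66-to-36 spk/s decay yields $AI \approx 0.33$, comfortably
  above threshold.

## Charge dosimetry

Delivered charge follows conservation over the pulse schedule:
$q = n_{sets} \sum_{1}^{n_{pulses}} \int_{t_1}^{t_2} I(t)\,dt$. The leading
factor is the number of sets (three in the study protocol, generalized to
`n_sets`). For rectangular pulses the integral is exact
(`amplitude * pulse_duration`); sampled waveforms integrate by the
trapezoidal rule. The study schedule — 20 stimuli of 3 s per set, three sets —
gives 0.018, 0.09 and 0.18 C at 100, 500 and 1000 µA. Electrode polarity is
metadata only. Charge is linear in every protocol parameter, which the tests
assert on a grid.

## Receptor tables and group statistics

The histology design has five groups (control, PD, PD + 100/500/1000 µA),
two receptor subtypes (AMPA, NMDA), and published group means ± SEM in
counts/mm². The generator reconstructs between-animal variability as
$SD = SEM \sqrt{n}$ (with the published $n$ = 6, 5, 3, 3, 3), draws each
animal-side density i.i.d. from a zero-truncated normal (the study found no
left/right difference; truncation is by redraw, preserving the mean to within
about 1%), and adds Poisson field-to-field noise (default five 0.15 mm²
fields per animal-side — a 400× field of view; both configurable, and
`field_noise = "none"` gives exact tables for degenerate tests). The AMPA
GVS-group SEMs are not published (only that AMPA was statistically
maintained), so the PD SEM is reused there.

The analysis unit is the per-(animal, side) mean density; the study does not
state whether fields or animals were its replicates, and animal-side means
are the conservative choice. All contrasts are two-sided two-sample t-tests,
pooled-variance by default (matching the behavior of the study's analysis
tool) with Welch as an option; no multiple-testing correction is applied,
matching the study, but a note is emitted whenever more than three tests run
in one invocation. Degenerate zero-variance inputs resolve by convention
(equal means: $p = 1$; unequal: minimal positive $p$, flagged).

**Reproducibility limits.** The published per-bar replicate structure cannot
be decomposed from the printed SEMs, so the study's p-values (e.g.
$1.85\times10^{-9}$ for the NMDA increase after PD) are not reproducible as
fixed targets; the package treats them as direction/trend properties. One
property deserves emphasis: the first step of the published NMDA
dose-response (165.86 to 160.58 counts/mm²) is approximately a 0.15-standard
deviation effect under the reconstructed variability — the study itself
reports $p = 0.82$ for it — so the *full* four-group monotone ordering is
recovered in well under half of simulated replicates. The direction of the
large effects (PD-vs-control increase for both receptors, the 500 µA and
1 mA decreases) is recovered essentially always.

## Numerical choices and degenerate inputs

* Time-rescaling grid: 1 ms; rates validated non-negative on the grid.
* Gamma draws arrive in chunks sized to the expected count to keep generation
  O(n); all generators restore the caller's RNG state and are pure functions
  of (spec, seed). Child seeds derive from the master seed and stay inside
  the 32-bit range.
* `runmed` width is forced odd; epochs with fewer spikes than the window pass
  through unsmoothed.
* Charges carry ordinary double precision: 100 µA × 180 s prints as 0.018 C
  but is not binary-exact; comparisons use relative tolerances.
* Problem sizes in the test suite (5,000+ ISIs for moment recovery, 50-unit
  populations for classification concordance, 200–1,000 seeds for calibration
  properties) were chosen so that 3-SE acceptance bands have comfortable
  power while the whole suite runs in a few minutes.

## Known limitations

* No refractoriness, bursting, or serial ISI correlation; no biophysical
  neuron model; no lesion dynamics.
* The tonic/phasic construction ($AI$, threshold 0.25) is this package's
  operationalization, not the study's definition.
* Stimulus frequency/amplitude for head motion are unpublished; gain values
  are only meaningful relative to a user-supplied amplitude.
* Receptor counts are consumed as tables; no image processing. Section
  thickness, stereology and spatial structure within VN are out of scope.
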