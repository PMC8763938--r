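---
title: "dualpath: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dualpath: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualpath)
```

## Scope

`dualpath` implements the analysis stack for studies of two radially
segregated populations of ventral-hippocampal (vH) neurons projecting to
prefrontal cortex (PFC): a superficial-layer population and a deep-layer
population with opposing activity signatures during anxiogenic
behaviour. The package covers five analyses plus their synthetic-data
generators:

1. **Layer clustering** — Gaussian mixture models over straightened-axis
   cell coordinates, component count selected by BIC.
2. **Dual-colour fiber photometry** — lock-in demodulation of two
   frequency-multiplexed LED carriers, autofluorescence correction,
   detrending and z-scoring.
3. **Peri-event statistics** — event-aligned epochs with
   baseline/pre/post window means and layer-difference scores.
4. **CRACM electrophysiology** — light-evoked response amplitudes,
   connectivity thresholds, paired ratios, intrinsic features.
5. **EPM behaviour** — zone classification, arm entries, open-arm
   metrics and the closed-loop stimulation gate.

Everything upstream of these tables and traces (imaging, tracking,
atlas registration, reconstruction) is out of scope: inputs are
coordinate tables, photoreceiver time series, sweep matrices, SWC trees
and head-position tracks.

## Layer clustering

Cell maps live in the unit square: a radial coordinate (0 = alveus
side, so the deep layer sits near 0 and the superficial layer near 1)
and a longitudinal coordinate along the straightened CA3-to-subiculum
field, where the CA1/subiculum border falls near 0.7. `fit_layer_gmm()`
fits full-covariance Gaussian mixtures with k = 1..6 by EM (10
k-means++ restarts, convergence tolerance 1e-4, covariance ridge 1e-6)
and records BIC = −2 logL + p ln n per candidate. Ties within 1e-6 go
to the smaller k. The fit is 2-D — radial and longitudinal jointly —
because the observed clusters separate radially while sharing the
longitudinal distribution, and a 2-D fit leaves that choice to the
data. Per-slice or pooled fits are both possible; fitting a single
pooled map is the package default workflow, with the `slice` column
available to split.

Components of a selected two-component model are named by radial-mean
order: nearest 0 is `deep`, nearest 1 is `superficial`. This naming is
a package convention (the data carry no labels); assignments are
maximum-posterior. For k ≠ 2, layer names are refused and component
indices are returned on request, so a surprising model selection can
never silently masquerade as a two-layer result.

The default synthetic cell map is the package's stated world: 500
cells, equal-weight layers at radial 0.15 and 0.85 (longitudinal 0.7),
per-axis SDs (0.08, 0.15). The radial separation is ~8.8 within-layer
SDs — comfortably past the ≥ 4 SD regime where BIC identification is
reliable — because the real maps show two well-resolved fluorescence
peaks at the radial extremes. Tracer rules default to CTXβ everywhere
and rabies at 0.8 (deep) / 0.2 (superficial), emulating the observed
restriction of excitatory-target-tracing to the deep layer.

## Photometry model and conditioning

The acquisition being emulated: a 470 nm LED sinusoidally modulated at
210 Hz excites GCaMP6f (green emission, deep layer, creOFF), a 565 nm
LED at 500 Hz excites RGeCO1a (red emission, superficial layer, creON),
and the photoreceiver output is sampled at 100 kHz. The generator's
carrier waveform is the offset sinusoid (1 + sin 2πft)/2 so envelopes
stay non-negative — the acquisition description says only "sinusoidally
modulated", and an AM envelope cannot be negative.

The generator produces one trace per emission sensor. Each sensor
carries its own envelope (bleach trend + calcium transient train +
autofluorescence coupling) on its matching carrier, plus the shared
autofluorescence artifact on the *other* carrier. This is the physics
that makes the cross-frequency autofluorescence estimate meaningful:
broadband autofluorescence is excited by both LEDs, so each sensor sees
it at both modulation frequencies, while the indicator signal rides
only on its own carrier. A single summed photoreceiver trace could not
support this estimate at all. The shared artifact is a smooth sum of
slow (0.005–0.05 Hz) sinusoids, shifted positive; transients are
difference-of-exponentials kernels (rise 0.05 s, decay 0.5 s —
GCaMP6f/RGeCO1a-plausible, since the source describes no transient
model); bleaching is a polynomial in normalised session time.

Processing chain (`process_session()`):

* **Demodulation** — quadrature lock-in: multiply by sine and cosine
  references at the carrier, low-pass both products, return
  4·√(I² + Q²), which maps a unit offset-sinusoid carrier to envelope
  1 and is invariant to the (unrecoverable) carrier phase. The
  low-pass is a 4th-order zero-phase Butterworth at 20 Hz: no filter is
  specified by the source; 20 Hz respects both the 50 Hz output Nyquist
  and the 290 Hz carrier gap.
* **Downsampling to 50 Hz** — anti-alias filter then decimation;
  output length is floor(duration × 50).
* **Settling trim** — 0.5 s removed from each end before any
  statistics (filter edge transients).
* **Detrending** — 3rd-order least-squares polynomial subtracted,
  applied on the 50 Hz trace. The original order of operations is
  unstated; detrending after downsampling matches the description of
  export at 50 Hz followed by bleaching correction, and both orders
  are available by composing the stage functions directly.
* **Autofluorescence regression** — each channel is regressed (OLS) on
  its own sensor's cross-frequency estimate; the fitted trace is
  subtracted.
* **z-scoring** — mean/SD over the whole session. A session-wide
  window is the plain reading of the source; a baseline-window z-score
  can be built from the stage functions if wanted.

The generator defaults (noise SD 0.02, transient rate 0.1/s, amplitude
1, autofluorescence gain 0.2) are assumptions, not reported facts — the
source gives no noise or transient statistics. They were chosen once as
plausible for fiber photometry at ~100 µW excitation and are not tuned.
Green tests on this generator establish that the chain recovers known
envelopes, removes programmed bleaching, and rejects cross-channel
leakage; they do not establish performance on hemodynamic or motion
artifacts, which the generator does not model.

## Peri-event statistics

Epochs are 12 s (−6 to +6 s) at 50 Hz, 600 samples, with half-open
`[start, end)` windows so edge samples are never double-counted.
Windows: baseline (−6, −4) s, pre (−2, 0) s, post (2, 4) s for open-arm
entry, (0, 4) s for closed-arm entry, (2, 4) s otherwise. One figure
legend in the source states a (−6, −5) baseline while the methods text
states (−6, −4); the methods value is the default and the legend
variant is one `window_spec(bl = c(-6, -5))` away. Baseline
subtraction recentres each epoch on its own baseline mean. Long epochs
are 20 s with baseline (−10, −8) s. Animal-level values are means of
event means. Incomplete epochs at recording edges are dropped and
logged, never padded. Events of different types are aligned
independently and epochs may overlap.

The programmed pattern generator (`gen_pattern_session()`) encodes the
qualitative two-layer signature as Gaussian bumps: superficial rises
after open-arm entry (+3 s, width 1 s); deep rises before entries
(−1 s), falls after open-arm entry and stays up after closed-arm entry.
It emits 50 Hz traces directly — carriers, bleaching and noise floors
are the demodulation suite's job — so the peri-event sign-pattern
criterion can run over 100 seeds inside its time budget. Default bump
amplitude 1 with noise SD 0.3 gives single-event SNR ~3, a realistic
regime for bulk photometry transients.

`holm_sidak()` implements the step-down Šidák adjustment
(adj_(i) = max_(j≤i) 1 − (1 − p_(j))^(m−j+1), clipped to 1) used for
the study's multiple comparisons; the inferential tests themselves
(ANOVAs, t-tests, Mann-Whitney) are deliberately not re-implemented —
they come from standard libraries.

## CRACM quantification

The averaged sweep, baseline-subtracted, is searched for its absolute
peak inside the response window; the amplitude is the mean over a 1 ms
window centred on the peak (so it sits slightly below the true peak — a
property the tests pin against the closed-form kernel). A cell counts
as connected when |amplitude| strictly exceeds 6 × the baseline SD of
the averaged trace. Design choices the source leaves open: baseline
window 50 ms immediately pre-stimulus, response window 2–50 ms
post-onset, peak found on the averaged trace (the description of 1-ms
averaging around "the peak" of averaged responses). The false-positive
behaviour of this statistic is *quantified*, not assumed: the
peak-search across the response window inflates the rate far above the
fixed-window Gaussian tail, and the tests compare the detector against
an independent Monte-Carlo implementation of the identical statistic —
at the 6 SD operating point (where both rates are ≈ 0) and at a lower
factor where the rate is measurable.

Intrinsic features: spike counts via 0 mV upward crossings with a 2 ms
refractory; bursting = first ISI < 10 ms at the lowest suprathreshold
step (the source shows bursting but does not define it); sag = steady
state (last 100 ms) minus the early minimum (first 300 ms) of the
−160 pA step, windows sized for 500 ms steps and configurable; τm from
a log-linear fit to the onset of the smallest hyperpolarising step; AP
half-width at half peak-to-threshold height with a 20 mV/ms threshold
criterion and interpolated crossings. Fast-spiking classification is a
k-means 2-partition on standardised (τm, half-width) with 10 restarts —
the source names the features but not the algorithm; FS+ is the
smaller-half-width cluster.

Paired ratios use magnitudes (voltage-clamp signs are a convention) and
report log10 alongside, matching the log-axis presentation of
superficial:deep, E/I and FS−:FS+ ratios.

## EPM analysis

Geometry is five disjoint rectangles (two open arms on the x-axis, two
closed arms on the y-axis, a 10 cm centre). Zone classification is a
head-point-in-polygon test — the head-entry criterion deliberately
includes stretch-attend postures. Position gaps ≤ 0.5 s are
interpolated; longer gaps become `off_maze` rather than guessed. Entry
detection debounces at 0.5 s (the source specifies no debounce; 0.5 s
suppresses tracking flicker at typical frame rates without eating real
visits); each qualifying visit also yields an `arm_end_reached` event
at the maximum distance from the centre.

Sessions are 9 min split into three 3-min epochs, stimulation in the
second. The latched gate turns on at the first centre/open frame inside
the stimulation epoch and stays on until the first closed-arm frame,
epoch end, or session end; a mouse already in the centre at epoch start
gets light at epoch start (the conservative reading of
position-conditional delivery). The constant variant is on for the
whole epoch regardless of position. Entry probability is open entries
over all arm entries per epoch — the source does not define the
denominator, so this choice is explicit and flagged. The exclusion
criterion (no open-arm entry in the first three minutes) is reported as
a flag by `ordinal_split()`-style consumers, never silently applied.

The synthetic walk is a frame-level Markov chain over
{centre, open1, open2, closed1, closed2} with arms connected only
through the centre; self-transition probabilities set geometric dwell
times (defaults: ~2 s centre, ~10 s arms at 25 fps, P(open|leave
centre) = 0.3 — an anxious-but-exploring occupancy profile). Rendered
positions run out and back along each visited arm with 1 cm Gaussian
jitter so zone classification is non-trivial. The chain's stationary
distribution (left unit eigenvector) is the oracle for occupancy tests.
What this generator does not emulate: wall-hugging thigmotaxis,
speed profiles, and head-direction dynamics — so green tests establish
zone/gate logic, not behavioural realism.

## Numerical choices

* Butterworth design is by bilinear transform with frequency
  pre-warping; coefficients were validated against an independent
  reference implementation during development. Zero-phase filtering
  pads by three settling times (3 fs/cutoff samples) with odd
  reflection, so zero initial conditions cannot leak into the kept
  span.
* EM declares convergence when the log-likelihood changes by less than
  1e-4 (relative); restarts that collapse a component (responsibility
  mass < 1e-10) are discarded; k = 1 uses the closed-form MLE.
* Degenerate inputs fail loudly: zero-variance z-scores, zero-variance
  autofluorescence regressors (fitted trace falls back to the signal
  mean, flagged), empty cell maps, cyclic SWC trees, non-stochastic
  transition matrices.
* All generators take integer seeds; a fixed seed gives bit-identical
  output. `run_demo()` derives per-stage seeds from one global seed by
  a documented affine map kept inside 32-bit range.

## Scaling and limitations

The config default acquisition rate is the full 100 kHz; tests, the
demo and the acceptance script simulate at 10 kHz (still ≥ 10× the
highest carrier, preserving the carrier arithmetic) and use 20–120 s
sessions so the whole suite runs in minutes on one CPU. Known
limitations: no isosbestic-channel correction (not part of this
acquisition), no motion/hemodynamic artifact model, no spike sorting or
kinetics beyond τm, no atlas registration, and group-level inferential
statistics are delegated to standard libraries by design.
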