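---
title: "Methods: contactless vital-sign estimation from RGB and thermal video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contactless vital-sign estimation from RGB and thermal video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalcam)
```

## The measurement problem

A thermal camera (256 × 192 temperature matrix) and an RGB webcam (nominally
640 × 480) observe a subject's face from roughly a metre away. Three vital
signs are read out without skin contact:

* **Body temperature (BT)** — a single raw-temperature pixel on the forehead
  midline, located `H1/3` above the eye midpoint, where `H1` is the vertical
  distance from the top of the face box down to the eye midpoint.
* **Heart rate (HR)** — cardiac blood inflow modulates the optical
  properties of facial skin. The per-frame means of the red, green and blue
  channels over a forehead box (half the face-box width, 0.4 of its height,
  centred on the BT point) carry a weak remote blood-volume pulse (rBVP).
* **Respiration rate (RR)** — exhaled air warms and inhaled air cools the
  nostril region, so the mean temperature of a nostril box (0.9 of the mouth
  width by 0.6 of the nose-to-mouth distance, centred on the nose tip)
  oscillates at the breathing frequency.

The forehead is preferred over the whole face for HR because it remains
visible when a face mask is worn. Landmarks (eyes, nose tip, mouth corners)
and the face box come from an external detector and enter through a CSV
sidecar; this package performs no detection itself.

Coordinates are 0-based with x rightward and y downward; boxes are
`(x_min, y_min, w, h)` with half-open extents. When a box is converted to a
pixel set, its edges are rounded to the nearest integer and the half-open
slice is taken; a clipped ROI smaller than 4 pixels is treated as invalid.
"Mouth width" is the horizontal distance between the mouth-corner
x-coordinates, and the "mouth middle point" their midpoint — the plain
reading of the geometric construction.

## Head-movement gating

Frames where the subject looks away are excluded before any extraction. The
deflection ratio is

$$ d = \frac{|T_x - \mathrm{Face}_x|}{\mathrm{Face}_{width}} $$

with \(T_x\) the eye-midpoint x and \(\mathrm{Face}_x\) the face-box centre
x. A frame is gated when \(d \ge 0.17\); the comparison is inclusive because
0.17 is the rejection boundary. Only horizontal turns are considered —
cameras are rig-mounted at face height, so vertical inclines are out of
scope. A window in which more than 30% of frames are gated is declared
invalid for every modality (the 30% figure is this package's choice; with
half a window gated, the surviving segment is shorter than the filters'
settling requirements).

## Two-camera registration

The cameras sit side by side in one plane, so mapping RGB pixel coordinates
onto the thermal grid needs only per-axis scale plus translation:
\((x, y) \mapsto (s_x x + t_x,\; s_y y + t_y)\). Rotation, shear, lens
distortion and perspective are deliberately excluded. The parameters are rig
calibration inputs (config keys `registration.sx/sy/tx/ty`, default
0.4/0.4/0/0, which maps a 640 × 480 frame exactly onto 256 × 192);
`fit_map()` estimates them by least squares from point correspondences but
is never run automatically. Streams are paired by nearest timestamp with a
tolerated skew of half an RGB frame period.

## The cardiac chain

Per 15-s window the chain is: band-pass each colour trace → normalize →
JADE ICA → source selection → EMD → peak detection → rate. The order
(filter first, then normalize, then separate) follows the published
processing sequence.

* **Band-pass.** Third-order Butterworth, 0.8–2 Hz (48–120 beats/min),
  applied forward and backward so peak times are not phase-shifted. The
  signal mean is removed before filtering: the implementation used for
  filtering does not match initial conditions, and a large DC level (colour
  means sit above 100 gray; nostril temperatures near 33 °C) otherwise
  injects an edge transient that dwarfs the passband signal. The input must
  cover at least `guard_periods` periods of the lower band edge —
  `3 × order` (9 periods, 11.25 s at 0.8 Hz) for the cardiac chain. The
  respiratory chain relaxes this to 2 periods, because 9 periods of 0.15 Hz
  would be 60 s and the analysis window is 15 s; two full periods are the
  minimum for which the interior of the window remains usable after the
  filter transient.
* **Normalization.** \(x' = (x - \mu)/\sigma\) per channel (sample SD), so
  channel gains do not dominate the mixing estimate.
* **JADE ICA.** Classic joint approximate diagonalization of the
  fourth-order cumulant matrices after whitening, implemented in the
  package. ICA component order is arbitrary, so components are returned in
  a deterministic order — descending magnitude of excess kurtosis — and
  sign-fixed so each source's largest-magnitude sample is positive. This
  makes "the second component" a reproducible notion across runs.
* **Source selection.** The conventional rule takes the second component as
  the pulse. That regularity is empirical, not structural, so a guard
  scores each source by *tonality*: the fraction of its total non-DC
  spectral power within ±0.15 Hz of its dominant in-band frequency. If the
  second component's tonality is below 0.8 × the best source's, the most
  tonal source is substituted and the result flagged. Tonality, rather than
  raw in-band power, is essential here: the sources are already
  band-limited by the preceding filter, so band-passed noise retains more
  than 90% of its power in-band and an in-band-power test can never reject
  it — but it spreads that power across the 1.2 Hz band instead of
  concentrating it at a line. On a 40-window calibration ensemble spanning
  both ROI scales used in this package, pulse components scored 0.89–0.98
  and noise components 0.22–0.60 (worst ratio 0.68), so the 0.8 relative
  threshold separates the classes with margin on both sides; it was frozen
  after that calibration.
* **EMD.** Standard sifting with cubic-spline envelopes through the local
  extrema (up to two extrema mirrored past each end so envelopes do not sag
  at the boundaries), Cauchy-type stop `SD < 0.2`, at most 10 sifting
  passes per mode and 10 modes. The intrinsic mode function with the
  greatest mean-square power is taken as the recovered rBVP; IMFs plus
  residue reconstruct the input exactly by construction. Mean-square rather
  than sum-of-squares power is used — the two are equivalent for selection
  at equal lengths.
* **Peaks and rate.** Local maxima with topographic prominence at least
  0.3 signal SDs and a 0.5-s refractory period (a 120 beats/min ceiling);
  ties are resolved by keeping the higher peak. The rate is
  `60 / mean(interval)` in beats/min.

## The respiratory chain

The registered nostril box is read from CLAHE-enhanced 8-bit renderings of
the thermal stream (contrast-limited adaptive histogram equalization,
clip limit 2, 8 × 8 tiles — conventional defaults; the renderer min–max
normalizes temperatures over a rolling 15-s window so a transient hot
object does not re-scale the whole recording). Body temperature, by
contrast, is always read from the *raw* temperature matrix — two distinct
data paths. The trace is band-passed to 0.15–0.5 Hz (9–30 breaths/min,
order 3, zero-phase), peaks are detected with a 2-s refractory period, and
`RR = 60 / mean(interval)`. Nostril temperature falls during inhalation —
opposite in sign to a force-based chest belt — but peak-interval rates are
polarity-invariant, so no inversion is applied.

## Signal quality screening

Both waveforms are screened by an ensemble-averaging signal quality index:
the template window length is the median peak-to-peak interval rounded to
the nearest odd sample count (so the peak sits exactly in the middle); each
complete pulse (edge-truncated windows are dropped rather than padded) is
correlated with the sample-wise mean template, and the SQI is the mean
Pearson correlation. Zero-variance pulses, for which correlation is
undefined, are excluded; if fewer than two informative pulses remain the
SQI collapses to 0. A window is used only when SQI strictly exceeds 0.8
(cardiac) or 0.7 (respiratory).

One screen proved necessary beyond the SQI. After narrow band-pass
filtering and EMD mode selection, *any* process — including white noise —
looks locally periodic, and measured SQI values for pure-noise windows are
0.92–0.94. The cardiac chain therefore additionally requires the selected
ICA source to show a concentrated spectral line (tonality ≥ 0.75) before a
window is declared valid; noise windows measure at most ~0.6 on this scale.
The respiratory chain has no ICA stage to supply this evidence and retains
the plain SQI rule — a known limitation: a nostril trace of pure
band-limited noise can pass its screen.

## Aggregation and evaluation

Recordings are analysed in 15-s windows with 50% overlap; window k starts
at `k · 7.5` s and only fully contained windows are evaluated. Per window,
BT is the median of the per-frame forehead lookups (robust to transient
occlusion). Frames with missing or gated ROIs leave gaps: gaps up to 0.5 s
are bridged by linear interpolation, longer gaps invalidate the window's
modality (across a whole recording, long gaps split the trace into
separately assessed segments). Agreement with a reference is summarised by
MAE ± SD of the absolute errors, the Pearson correlation (reported as
undefined when either side has no variance), and Bland–Altman bias with
`bias ± 1.96 · SD` limits of agreement.

## The synthetic test bed

`fixture_spec()` / `generate_fixture()` emulate the rig with known ground
truth: forehead pixels modulated at the cardiac frequency with
channel-specific gains (green strongest, 1 gray level, mimicking
plethysmographic dominance; second harmonic at 0.25 amplitude for a
pulse-like asymmetric waveform), per-pixel sensor noise of 2 gray levels,
and a shared per-frame illumination fluctuation of 0.3 gray — the
component that does not average out over the ROI and therefore sets the
series-level noise floor. The thermal stream holds a 33 °C face patch over
a 28 °C background, a nostril patch oscillating with 0.3 °C amplitude over
a slow random-walk drift (0.005 °C/frame) that exercises the band-pass
filter, 0.05 °C per-pixel noise (a typical uncooled-core noise floor), and
a constant-temperature forehead point. Landmarks are rigid, with an
optional per-frame horizontal eye-midpoint offset to exercise the
deflection gate, and thermal geometry is the registration map applied to
the RGB geometry. Both streams default to 25 frames per second; the rates
are independent fields so mismatched-rate handling can be exercised.

Two memory-lean generators, `fixture_channel_series()` and
`fixture_nostril_series()`, synthesize only the ROI pixel block per frame
(identical signal model) and feed it through the real extraction
operations; they make 50-window parameter-recovery studies cheap. The test
suite runs the full-frame pipeline on reduced frames (160 × 120 and
128 × 96, with the face geometry scaled proportionally) and recordings of
16–30 s; the recovery studies use 50 windows of 15 s at the default
geometry. On these conditions the cardiac chain recovers HR with an MAE
well under 1 beat/min and the respiratory chain RR within ~0.3 breaths/min.

What the generator does *not* emulate — and hence what passing tests do not
demonstrate — includes real skin chromophore dynamics and ballistocardiac
motion, detector jitter in the landmarks, illumination with spectral
structure, mask fabric thermodynamics (a mask is approximated simply as a
larger respiratory amplitude), emissivity and ambient-temperature effects,
and camera synchronization drift. Accuracy figures obtained on fixtures are
statements about the processing chain, not about field performance.

## Numerical conventions and edge cases

* Pixel lookup for BT uses `floor(x + 0.5)` (round-half-up) for
  determinism; the matrix entry is returned exactly, with no interpolation.
* Degenerate geometry (eye midpoint above the box top, coincident mouth
  corners, zero-area clipped ROIs) flags the frame invalid rather than
  raising, so one bad detection cannot abort a recording; stream-level
  errors (landmark indices outside the stream) do raise, with the frame
  index named.
* JADE refuses rank-deficient channel sets (smallest covariance eigenvalue
  below 1e-10 of the largest) and inputs shorter than 250 samples, where
  fourth-order cumulant estimates become unstable.
* All stages are deterministic for fixed input: identical windows produce
  identical results with no hidden RNG use.
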