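# vitalcam

Contactless estimation of heart rate, respiration rate and forehead body
temperature from paired RGB and thermal camera streams.

Screening people's vital signs at building entrances — without contact
sensors, at a social distance, and with face masks on — requires reading
physiology out of video. `vitalcam` implements the full processing chain
for a two-camera rig: an RGB webcam watching the face and a thermal camera
delivering raw 256 × 192 temperature matrices.

## Method

From per-frame facial landmarks (an external detector's output, supplied as
a CSV sidecar) three regions of interest are constructed:

* **BT point** — on the forehead midline, `H1/3` above the eye midpoint
  (`H1` = distance from the box top to the eye midpoint). Body temperature
  is the raw temperature matrix entry at that point.
* **HR box** — forehead rectangle (0.5 × face width, 0.4 × face height)
  centred on the BT point.
* **RR box** — nostril rectangle (0.9 × mouth width, 0.6 × nose-to-mouth
  height) centred on the nose tip.

Non-frontal frames are gated by the deflection ratio
`d = |T_x − Face_x| / Face_width ≥ 0.17`, and RGB coordinates map onto the
thermal grid through a scale-plus-translation affine calibration
`(x, y) ↦ (s_x x + t_x, s_y y + t_y)`.

Per 15-s sliding window (50% overlap):

* **HR**: channel means over the HR box → 3rd-order zero-phase Butterworth
  band-pass 0.8–2 Hz → per-channel standardization → JADE ICA (fourth-order
  cumulant joint diagonalization, implemented here) → pulse-source
  selection with a spectral-tonality guard → empirical mode decomposition,
  keeping the maximum-power IMF → peak detection →
  `HR = 60 / mean(peak interval)` beats/min.
* **RR**: CLAHE-enhanced nostril means from rendered thermal frames →
  band-pass 0.15–0.5 Hz → peak detection →
  `RR = 60 / mean(peak interval)` breaths/min.
* **Quality**: ensemble-averaging SQI — mean Pearson correlation between
  individual pulses and their peak-centred average template — must exceed
  0.8 (HR) / 0.7 (RR) for a window to count.

A synthetic fixture generator produces RGB frames, thermal matrices and
landmark files with known ground-truth HR/RR/BT, so every stage is testable
without cameras. See `vignettes/vitalcam-methods.Rmd` for the full model,
parameter choices and limitations.

## Worked example

```r
library(vitalcam)

# a 15-s synthetic recording with known truth: HR 72 bpm, RR 15 brpm
ch <- fixture_channel_series(fixture_spec(hr_bpm = 72, seed = 1))
estimate_hr(ch$r, ch$g, ch$b)
#> <rbvp_result: HR 71.8 bpm, SQI 0.977, 18 peaks>

x <- fixture_nostril_series(fixture_spec(rr_brpm = 15, seed = 1))
estimate_rr(x$x)
#> <resp_result: RR 15.3 brpm, SQI 0.975, 4 peaks>
```

The HR readout is 71.8 beats/min against a 72 beats/min truth with a signal
quality of 0.977 (threshold 0.8); the respiration readout is 15.3
breaths/min against 15, quality 0.975 (threshold 0.7). Full recordings are
processed per subject and window with `run_subject()`, which returns one
row per window (estimates, SQI values, validity flags and reason codes,
gated-frame fraction) via `as.data.frame()`.

The same pipeline is scriptable from the shell:

```sh
exec/vitalcam synth --spec spec.yaml --out fixture/
exec/vitalcam run --rgb fixture/rgb --thermal fixture/thermal \
    --landmarks fixture/landmarks.csv --out results.csv
exec/vitalcam eval --results results.csv --reference ref.csv --modality hr
```

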