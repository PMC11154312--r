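# rppgfatigue

Contact-free driver fatigue detection from camera-derived signals, as a
complete, testable R pipeline. Two modalities are extracted and fused per
60 s window:

* a **physiological channel**: a remote photoplethysmography (rPPG) pulse
  trace — the spatial mean of facial skin pixels per video frame — from
  which heart-rate-variability (HRV) features are derived;
* a **behavioural channel**: PERCLOS (fraction of eyes-closed frames) and
  yawn rate from 5-point facial landmark geometry.

The package is aimed at biosignal researchers who have per-frame ROI
intensities and landmark streams (from any face-analysis front end) and
want a reproducible, fully seeded path from raw traces to per-window
fatigue decisions — plus a ground-truthed synthetic-signal generator so
every stage can be validated without video data.

## The method

**Pulse separation.** The raw trace `A_t` is embedded in an M × K Hankel
trajectory matrix and decomposed by SVD (singular spectrum analysis);
components whose dominant frequency lies in the cardiac band (0.8–4 Hz)
are kept and reconstructed by anti-diagonal averaging. A 1 s moving-average
baseline is subtracted (respiratory drift) and a zero-phase Hamming FIR
bandpass finishes the cleaning.

**Beat detection.** An improved Pan–Tompkins detector: five-point
derivative → peak normalization → Shannon energy `-x² ln x²` →
moving-window integration into an envelope → adaptive dual thresholds
(`T1 = NT + (ST − NT)/4`, `T2 = T1/2`, exponential updates
`ST ← DP/8 + 7ST/8`) with a 200 ms refractory period and search-back over
gaps longer than 1.66× the mean of the last eight DD intervals. Detected
envelope peaks are localized onto waveform maxima, so DD intervals are
true peak-to-peak times.

**HRV features.** MEAN and population SD of the DD intervals; the interval
series is resampled to a 4 Hz tachogram (cubic spline) and the Welch PSD —
Hamming segments of length L advancing by L/4, normalized by
`U = (1/L) Σ D(m)²` — yields LF (0.04–0.15 Hz), HF (0.15–0.40 Hz) and
their ratio LF/HF, the sympathovagal balance index that rises with
fatigue.

**Facial features.** Eye and mouth region boxes from the 5 landmarks
(rotation from the interocular line, `h = w/2`; mouth box from the
nose-to-lip-line distance d, spanning d/2 to 5d/3), per-frame open/closed
and yawn states, and exact per-window rates
`P = closed frames / 1200`, `L = yawn frames / 1200`.

**Fusion.** Two 1-D CNNs (heart-rate model: input 1024, 3×32 filters,
kernels 16/8/4, FC 256/128; face model: input 600, 3×24 filters, kernels
10/5/3, FC 128/64) produce per-window class probabilities that a
bidirectional LSTM fuses into the final per-window decision. Evaluation
uses `Se = TP/(TP+FN)`, `+P = TP/(TP+FP)`, `Acc = TP/(TP+FP+FN)` and the
mean absolute DD−RR interval error.

## Worked example

```r
library(rppgfatigue)

# a labelled synthetic session: 3 windows of 60 s in the fatigue regime
sess <- simulate_session(preset = "fatigue", n_windows = 3, seed = 7)

# train the model stack on synthetic regimes (deterministic, ~2 min on CPU)
models <- train_fatigue_models(seed = 42)

report <- run_pipeline(sess, models = models)
print(report)
```

```
Session report: 3 windows, 200 beats (config 43df2b1b)
 window mean_s  sd_s lf_hf perclos yawn_rate p_fatigue_fused decision
      1  0.851 0.196 0.244    0.35      0.12               1 fatigued
      2  0.906 0.147 0.281    0.35      0.12               1 fatigued
      3  0.898 0.155 0.321    0.35      0.12               1 fatigued
```

Each row is one 60 s window: the mean and SD of the inter-beat (DD)
intervals in seconds, the Welch LF/HF ratio, the exact PERCLOS and
yawn-rate fractions, the fused fatigue probability and the decision. In
the fatigue regime the mean interval is long (low heart rate), interval
variability is elevated and over a third of frames have closed eyes, so
every window is called fatigued. (Session-level SD and LF/HF are computed
from *detected* beats and carry extraction noise — see the methods
vignette for why they differ from the generator's ground-truth values.) Intermediate stages are exposed
individually (`ssa_denoise()`, `detect_beats()`, `hrv_features()`,
`window_rates()`, `evaluate()`), and a thin command-line wrapper lives at
`inst/cli/fatigue-pipeline.R` (`simulate`, `run`, `train` subcommands).

## What is out of scope

Face detection, skin segmentation (superpixels) and landmark regression
are published components with mature implementations elsewhere; this
package consumes their outputs (per-frame means or masks, landmark CSVs)
through a provider interface. See `vignettes/methods.Rmd` for the full
model description, parameter defaults and known limitations.
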