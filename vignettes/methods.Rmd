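---
title: "Methods: from facial intensity traces to fused fatigue decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from facial intensity traces to fused fatigue decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rppgfatigue` implements a contact-free, multi-modal driver-fatigue
detection pipeline. Two information channels are extracted from camera
data — a remote photoplethysmography (rPPG) pulse channel carrying
heart-rate-variability (HRV) information, and a facial-landmark channel
carrying eyelid and mouth behaviour — and fused per 60 s window by a
bidirectional LSTM over the outputs of two 1-D convolutional classifiers.
This vignette explains each stage, its assumptions, the tunable parameters,
and the design decisions taken where the method description left choices
open. Everything is exercised on synthetic, fully ground-truthed signals;
no statement below depends on data the test suite does not generate itself.

## 1. The rPPG trace

The raw observable is the spatial mean of the skin pixels inside a facial
region of interest (ROI), one scalar per frame at `fs` frames/s (default
30). `spatial_average()` computes the in-mask mean; `assemble_trace()`
collects per-frame means into a `raw_trace` with frame interval `1/fs`, and
`trace_windows()` provides the sliding 30 s / 1 s analysis scheme typical
for frame-rate rPPG.

Face detection, skin segmentation and landmark regression are *not*
implemented: they are published components (Haar cascades, SLIC
superpixels, MTCNN) with mature implementations elsewhere. The package
consumes their outputs through a provider interface — per-frame masks or
pre-averaged traces, and per-frame 5-point landmark streams read from CSV —
and `select_roi()` implements only the deterministic argmax-by-score
candidate selection (ties to the lowest index). The synthetic ROI generator
`simulate_roi_frames()` builds pixel arrays whose masked mean reproduces a
chosen trace exactly, so the averaging path is testable without video.

## 2. Pulse separation: SSA, detrending, bandpass

Blind-source-separation methods assume source orthogonality that
physiological channels do not satisfy, so the pulse is separated by
**singular spectrum analysis**: the trace is embedded into an `M x K`
Hankel trajectory matrix (`ssa_embed()`, entry *(i, j)* = sample *i+j-1*),
decomposed by SVD (`ssa_decompose()`), and per-component series are
recovered by anti-diagonal averaging (`ssa_reconstruct()`).

Key numerical choices:

* **Embedding window `M`** defaults to `fs` samples (1 s), one cardiac
  cycle at 60 bpm — long enough that a pulse pair (sine/cosine-like
  component couple) separates from baseline drift, short enough that the
  SVD of the `M x K` matrix stays cheap. Configurable.
* **Sign convention**: each left singular vector is flipped so its
  largest-magnitude entry is positive, making the decomposition
  deterministic.
* **Component selection** (`select_pulse_components()`): a component is
  kept when the dominant discrete-Fourier frequency of its reconstructed
  series lies in the cardiac passband (0.8–4 Hz, i.e. 48–240 bpm). An empty
  selection is a legal, flagged outcome; the pipeline then falls back to
  filtering the raw trace.
* The SVD identity `P_i = sigma_i V_i` is used for the component matrices.
  Some descriptions of this construction print the eigenvalue
  `lambda_i = sigma_i^2` in place of the singular value there, but that
  version does not reconstruct the trajectory matrix, so the standard
  identity is implemented.
* **Anti-diagonal divisor**: the mean over each anti-diagonal uses the
  count of entries actually on that anti-diagonal (standard diagonal
  averaging), which makes full-component reconstruction the exact identity.

The selected components are summed, then **moving-average detrended**: a
centred 1 s moving mean is used as a slow baseline estimate and
*subtracted*. A plain moving average is a low-pass and would *retain*
respiratory-band interference rather than remove it; using its output as a
baseline-to-subtract is what actually removes sub-cardiac drift. A
`literal_ma = TRUE` mode applies the trailing moving mean as printed
(output shorter by `L - 1` samples) for users who want the textbook
operator. Finally a zero-phase Hamming-window FIR bandpass (0.8–4 Hz,
3 s of taps) removes out-of-band noise.

## 3. Beat detection

`detect_beats()` implements an improved Pan–Tompkins chain adapted to pulse
waveforms:

1. **Five-point derivative** (`five_point_derivative()`), exact for
   polynomials up to degree 4; the two samples at each edge use edge
   replication.
2. **Peak normalization** to max |y| = 1, the precondition of
3. **Shannon energy** `-x^2 ln(x^2)`, which maps all samples positive and
   emphasises medium-intensity slopes (maximum 1/e at |x| = e^(-1/2)) over
   both extremes — more robust than squaring for smooth pulse upstrokes.
4. **Moving-window integration** over `round(0.15 * fs)` samples into a
   smooth envelope. Two window rules circulate for this stage (0.18·fs, and
   a 30-sample/150 ms worked example at 200 Hz, i.e. 0.15·fs); the concrete
   worked value is taken as the default and 0.18 s remains available
   through the argument.
5. **Candidate peaks** are strict local maxima of the envelope (plateaus
   take the leftmost sample) with a minimum topographic prominence of 5% of
   the envelope maximum. The prominence floor is this package's candidate
   definition: at 30 frames/s the 4–5-sample integration window leaves
   micro-ripples on the envelope, and if those count as candidates they
   flood the noise-threshold update and drag the decision threshold below
   genuine noise humps.
6. **Adaptive dual thresholds**: initial signal threshold `ST` = (max
   candidate peak in the first 3 s)/3 and noise threshold `NT` = (mean
   candidate peak)/2; each signal peak updates `ST <- DP/8 + 7 ST/8`, each
   sub-threshold peak updates `NT` likewise, and the decision thresholds
   are always `T1 = NT + (ST - NT)/4`, `T2 = T1/2`. These two identities
   hold after *every* update and are asserted in the tests; repeated signal
   updates with constant `DP` converge `ST -> DP` geometrically with ratio
   7/8.
7. **Refractory period** 200 ms: candidates inside it are ignored entirely.
8. **Search-back**: when the current inter-beat (DD) interval exceeds 1.66
   times the mean of the last eight DD intervals, the gap is rescanned with
   the lower threshold `T2`; a recovered peak applies the faster refresh
   `ST <- DP/4 + 3 ST/4` and is marked with provenance `"searchback"`.
9. **Localization**: the envelope tracks slope energy, so its peak sits
   roughly an upstroke ahead of the waveform maximum (~0.13 s for a 0.5 s
   pulse). Each accepted candidate is therefore mapped to the *nearest
   local maximum of the input waveform* within 0.25 s, and a candidate that
   localizes onto the previous beat (the falling-slope energy hump) is
   treated as a duplicate and skipped. Reported beat times index the
   waveform, so DD intervals are true peak-to-peak times; on noiseless
   synthetic trains every beat is localized within one frame.

Beats inside the 3 s initialization span are excluded by default (their
thresholds are retrospective); `include_init = TRUE` keeps them.

Two behavioural notes verified on synthetic data: because Shannon energy
compresses amplitude differences, beats attenuated to 40% amplitude still
clear the primary threshold — search-back only becomes the recovery path at
much deeper attenuation (around 10–15%, between `T2` and `T1`); and the
final beat of a record can never be recovered by search-back, because no
later beat closes its gap.

## 4. HRV features

`hrv_time_domain()` returns the mean and the *population* (divisor-N)
standard deviation of the DD intervals, as the method defines them.
Spectral features require an evenly sampled series, so
`build_tachogram()` interpolates the (beat time, interval) pairs with a
natural cubic spline onto a 4 Hz grid — a PSD of unevenly spaced intervals
is otherwise undefined, and 4 Hz comfortably covers the 0.04–0.40 Hz HRV
bands.

`welch_psd()` averages Hamming-windowed segment periodograms, each
normalized by the window-power factor `U = (1/L) sum D(m)^2`. Segments of
`L` samples (default 256, i.e. 64 s at 4 Hz) advance by `L/4` — the
"quarter" scheme as printed, which gives 75% overlap between neighbours; a
conventional 50%-overlap mode is available (`overlap = "half"`). Only fully
contained segments are used: `floor((N - L)/step) + 1` of them. The PSD is
returned one-sided as power per Hz, so its integral approximates the series
variance (checked against Parseval on white noise). `band_powers()`
integrates the standard LF (0.04–0.15 Hz) and HF (0.15–0.40 Hz) bands by
the trapezoid rule; the band edges are the field's convention, since the
method text never defines them, and `HF = 0` yields an `Inf` ratio flag
rather than an error.

On simulated tachograms with sinusoidal LF/HF structure the analytic power
ratio `(lf_amp/hf_amp)^2` is recovered with ~3% median relative error over
ratios in [0.5, 4] (the acceptance suite requires < 15%).

## 5. Facial features

From a 5-point landmark set (eyes, nose, lip corners), `eye_boxes()` builds
rotated eye boxes: rotation = angle of the interocular line, width = 0.6 ×
interocular distance, height = width/2. The 0.6 scale is this package's
choice — the box width is never tied to a measurable quantity in the method
text, and some scale is needed to make the `h = w/2` rule operational.
`mouth_box()` drops a perpendicular of length `d` from the nose to the
lip-corner line and spans from `d/2` on the nose side to `5d/3` beyond
(height `13d/6`), rotated with the lip line. Both constructions are
translation- and rotation-equivariant (property-tested).

`classify_states()` turns per-frame openness scores into eye
(`open`/`closed`) and mouth (`normal`/`yawn`) states by thresholding, with
a minimum-run-length rule for yawns (default 1 frame so that simulator
round trips are exact; raise it for noisy real scorers). A fitted
classifier — e.g. the face CNN — can be plugged in instead.
`window_rates()` computes PERCLOS and the yawn-frame rate as exact count
ratios over a 1200-frame window (60 s at 20 fps; the counts, not the
durations, define the features, and both are configurable).

## 6. The two CNNs and the BiLSTM fusion head

Two small 1-D CNNs are specified by their architectures: the heart-rate
model (input 1024; three conv layers of 32 filters, kernels 16/8/4; FC
256/128; softmax over two states) and the face model (input 600; 24
filters, kernels 10/5/3; FC 128/64). No pooling is inserted — none is part
of the stated architectures — so the conv stack is flattened directly.
Convolutions are evaluated as patch-matrix products (im2col), training is
Adam (lr 1e-3, batch 32) on softmax cross-entropy with inverted dropout
(rate 0.5) after each fully connected layer, and every forward pass in
evaluation mode is deterministic. Inputs are standardized with training
statistics stored in the fitted object.

The input compositions are package conventions (the architectures fix only
the lengths):

* `build_hr_input()`: per-second instantaneous HR (from the tachogram), SD
  over a trailing 20 s window, and LF/HF over a trailing 40 s window
  (evaluated every 4 s and interpolated), concatenated channel-wise and
  linearly resampled to 1024 — so the first third of the vector carries HR
  slots, then SD, then LF/HF.
* `build_face_input()`: eye openness averaged into 0.2 s bins (300 values)
  followed by mouth openness bins (300 values).

`lstm_step()` implements the gate equations with sigmoid gates and tanh
candidate state. The output equation is implemented **as printed**,
`h_t = Gamma_o * C_t`, without the conventional tanh on the cell state;
`variant = "standard"` restores `h_t = Gamma_o * tanh(C_t)`. Both variants
are verified against an independent scalar-loop reference cell. The fusion
head (`fit_bilstm()`) runs one LSTM forward and one backward over the
sequence of per-window `[hr probabilities, face probabilities]` vectors,
concatenates the two hidden states per window, and maps them through a
learned softmax head — the "weighting" of the two models is learned, since
its exact form is unspecified. Training is full backprop-through-time with
Adam; reversing the sequence while swapping the direction parameters yields
exactly reversed predictions (a structural symmetry that is tested).

Evaluation metrics follow the printed forms: `Se = TP/(TP+FN)`,
`+P = TP/(TP+FP)`, and notably `Acc = TP/(TP+FP+FN)` *without* a
true-negative term; since that differs from conventional accuracy, the
conventional `(TP+TN)/total` is reported alongside in `evaluate()`.

## 7. The synthetic-data generator

The generator defines the study conditions for every test:

* **RR series** (`simulate_rr_series()`): interval *i* = base +
  LF-sinusoid + HF-sinusoid (evaluated at the cumulative beat time) +
  Gaussian jitter; the analytic LF/HF power ratio `(lf_amp/hf_amp)^2` is
  the spectral ground truth. Configurations that would produce a
  non-positive interval are rejected.
* **Pulse waveform** (`render_pulse_waveform()`): one raised-cosine pulse
  of width 0.5 s per beat (the morphology is unspecified upstream;
  raised-cosine is smooth, unimodal and configurable), plus a 0.2 Hz drift
  sinusoid for respiration and white Gaussian noise.
* **Eye/mouth streams** (`simulate_eye_state_stream()`): exactly
  `round(fraction × frames)` closed/yawn frames placed in
  exponential-length runs, so ground-truth fractions are exact count
  ratios.
* **Regimes** (`regime_params()`): relative to awake (72 bpm, LF/HF ≈ 0.5,
  jitter 8 ms, PERCLOS 0.08, yawn rate 0.01), the fatigue regime has lower
  HR (62 bpm), higher LF/HF (≈ 4.8), more jitter (22 ms, hence higher SD),
  PERCLOS 0.35 and yawn rate 0.12. The *directions* follow drowsiness
  physiology (sympathetic dominance raises LF/HF; interval variability and
  eyelid closure rise); the *magnitudes* are free parameters fixed once at
  values that give clearly separated regimes, because no quantitative
  effect sizes are available upstream. All randomness derives per-stream
  from one root seed (`derive_seed()`), so identical seeds give identical
  sessions.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: realistic PPG morphology (dicrotic notch,
amplitude modulation), motion artefacts and illumination changes,
landmark-regression noise, or inter-subject variability of the fatigue
effect sizes. One concrete consequence observed in testing: band-limiting a
raised-cosine train to 0.8–4 Hz keeps only ~3 harmonics, and the
truncation ringing produces mid-interval envelope humps that can cause
extra detections on *very clean* session traces, inflating the
window-level SD feature relative to RR ground truth (noisier traces raise
the noise threshold and suppress the effect). End-to-end regime decisions
are unaffected, but absolute session-level SD values should be read with
that caveat.

## 8. Problem sizes and determinism

The test and acceptance workloads are sized for a single CPU: SSA identity
on 100 series of 900 samples; detector exactness on five 30 s trains;
robustness on twenty 60 s traces at SNR 10 dB; LF/HF recovery on fifty
300 s RR series; CNN training on 120 samples per model for 20 epochs and
BiLSTM fusion on 30 eight-window sessions for 30 epochs (about two minutes
of training in total). Every stochastic step is seeded; the full pipeline
writes byte-identical reports when re-run with the same configuration, and
the report metadata carries the configuration hash and seed.

## 9. Known limitations

* The upstream face-analysis stack (detection, segmentation, landmarks) is
  out of scope; real deployments must supply those streams.
* The printed LSTM output equation (no tanh on the cell state) is the
  default for fidelity; users wanting the conventional cell should pass
  `variant = "standard"`.
* The `Acc` metric without TN penalizes false positives and false
  negatives but ignores correct rejections; compare models on the
  conventional accuracy as well.
* PERCLOS windows assume a complete, gap-free frame stream; missing frames
  raise an error listing the gaps rather than being imputed.
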