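# laparosound

Acoustic characterization of laparoscopic trocar adapters and
channel-adapted classification of electrosurgical (diathermy) sounds.

## The problem

Electrosurgery produces tissue-dependent sound — cutting liver does not
sound like coagulating fascia — and a spectrogram classifier trained on
microphone recordings can recognize the tissue being treated. Bringing
that idea into the operating room requires routing sound out of the
insufflated abdomen through an adapter mounted on a trocar, and every
adapter is an acoustic channel that colors the signal. A model trained on
a clean reference microphone degrades when it hears the same sounds
through an attenuating adapter (channel shift).

`laparosound` implements the full analysis chain for this problem, for
researchers studying surgical audio sensing or any comparable
channel-shift scenario:

1. **Channel measurement.** Maximum length sequences (MLS) — pseudo-random
   ±1 excitations of period 2^m − 1 with circular autocorrelation
   (2^m − 1, −1, …, −1) — and impulse-response (IR) recovery by circular
   cross-correlation (`generate_mls()`, `estimate_ir()`).
2. **Channel description.** Transfer functions H(ω) from IRs, and the
   relative transfer function against a reference microphone path,

   ΔH(ω) = 20·log10( |H_adapter(ω)| / |H_ref(ω)| )  [dB],

   with 1/6-octave Savitzky–Golay smoothing and band-average summaries
   (`tf_from_ir()`, `relative_tf()`, `smooth_fractional_octave()`,
   `band_average()`).
3. **Channel simulation.** Convolution of recordings with an adapter IR,
   y[n] = (f ∗ g)[n], so one reference dataset yields an
   adapter-specific dataset without re-recording (`convolve_signal()`,
   `convolve_dataset()`).
4. **Classification.** A 96×64 log-mel front end (mono 16 kHz, 100 Hz
   high-pass, 0.98 s windows at 75% overlap, 25 ms/10 ms STFT, 64 mel
   bands over 125–7500 Hz), idle-class balancing, a recording-level
   80:10:10 split, a compact trainable classifier with ADAM/RMSprop grid
   search and best-validation-loss model selection, and fine-tuning on
   convolved training data to adapt the model to each channel
   (`patches_from_audio()`, `train_classifier()`, `grid_search()`,
   `fine_tune()`).
5. **Evaluation.** Confusion matrices, mean accuracy, macro precision
   (mAP), macro recall (mAR), and F1 = 2·mAP·mAR/(mAP + mAR)
   (`evaluate_predictions()`, `f1_from_pr()`,
   `summarize_across_testsets()`).

Because the original recorded dataset is not public, the package includes
a first-class synthetic-data module: labelled diathermy-like sounds
(band-limited crackle bursts over a pink-noise floor, five classes:
liver, muscle, fat, fascia, idle) and synthetic adapter IRs designed as
minimum-phase FIRs from magnitude breakpoints, matching the published
qualitative channel profiles (near-flat −9.4 dB; roll-off from 200 Hz;
roll-off from 300 Hz reaching ≈ −40 dB at 1 kHz).

## Worked example

```r
library(laparosound)

# Design the silicone-tube channel and inspect its relative TF
ref  <- synth_adapter_ir(default_channel_profile("reference"))
tube <- synth_adapter_ir(default_channel_profile("tube"))
rtf  <- relative_tf(tf_from_ir(tube), tf_from_ir(ref))
rtf$delta_db[which.min(abs(rtf$freqs_hz - 1000))]
#> [1] -39.89509        # ≈ -40 dB at 1 kHz

dual <- synth_adapter_ir(default_channel_profile("dual_channel"))
band_average(relative_tf(tf_from_ir(dual), tf_from_ir(ref)), 100, 7500)
#> [1] -9.4             # flat channel, -9.4 dB band average

# Measure an IR through a simulated MLS loop and verify the recovery
mls <- generate_mls(15)
rec <- simulate_mls_measurement(mls, tube, periods = 4, noise_db = -30)
est <- estimate_ir(mls, rec)

# Channel-shift experiment on synthetic data (about 2 min on one CPU)
res <- run_channel_shift_experiment(n_per_class = 40, seed = 42)
c(clean = res$macc_clean, shifted = res$macc_shifted,
  finetuned = res$macc_finetuned)
#>     clean   shifted finetuned
#>    1.0000    0.5320    1.0000
```

The three numbers are patch-level mean accuracies of the same classifier:
trained and tested on the reference channel (`clean`), tested on
tube-convolved audio without adaptation (`shifted` — the channel-shift
degradation), and after fine-tuning on tube-convolved training data
(`finetuned` — the recovery). The qualitative pattern — strong
degradation under the heavily attenuating tube channel, recovery after
fine-tuning — mirrors the published finding; absolute values are
properties of the synthetic data, not of the original recordings.

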