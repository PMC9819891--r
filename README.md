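# emomap

Tools for studying how music listening shifts emotional state, for
researchers working with EEG-based emotion recognition and music information
retrieval. The package implements three connected layers:

1. **EEG emotion recognition.** Multichannel EEG (channels x samples, e.g.
   the 32-electrode 10–20 montage at 128 Hz) is denoised with a db4 wavelet
   hard-threshold rule — noise level σ̂ = median(|d₁|)/0.6745 from the finest
   detail coefficients, one global minimax threshold
   λ = σ̂ (0.3936 + 0.1829 log₂E) for signal length E > 32 (λ = 0
   otherwise) — band-passed to 4.0–45.0 Hz, decomposed by a cascaded db4
   filter bank into the classical δ/θ/α/β/γ bands, and summarized per
   channel and band by the average log power spectral density
   AvgPSD = (1/P) Σᵢ 10 log₁₀ Pxxᵢ from an 8-segment, 50%-overlap Hamming
   Welch periodogram.
2. **Music emotion classification.** Tracks are merged to mono, cut into
   15-second clips, and described by a 21-dimensional vector: 13 MFCCs,
   spectral centroid, spectral flux, zero crossings, RMS, tempo (BPM) and
   pulse clarity, a Krumhansl–Kessler major/minor mode score, and
   Plomp–Levelt sensory roughness.
3. **Emotion mapping.** Valence–arousal ratings (1–9 scale) map to a
   20-emotion vocabulary and to HV/LV x HA/LA quadrants; before/music/after
   records yield conditional transition tables
   P(after | before, music type) with parallel-coordinate exports.

Both recognition layers share an RBF-kernel SVM harness (libsvm via e1071)
with min–max scaling fitted on training folds, grid search over
C ∈ 2^{-5..15}, γ ∈ 2^{-15..3}, seeded stratified 10-fold cross-validation,
and EEG channel ranking / top-k selection. Seeded generators produce
synthetic EEG, music clips, and transition records with known ground truth,
so the entire chain runs and is tested without any external data.

## Worked example

```r
library(emomap)

# Synthetic EEG: 4 classes x 40 trials, 32 channels, one band boosted 3:1
sim <- simulate_eeg(eeg_sim_spec(seed = 2001))
tbl <- eeg_feature_table(sim$recordings, sim$labels)   # 160 x 128 features
fit <- emotion_svm(tbl[, !(names(tbl) %in% c("trial_id", "label"))],
                   tbl$label, svm_config(folds = 10, seed = 2002))
print(fit)
```

```
<emotion_svm> RBF-kernel SVM
<emotion_cv> 160 instances, 4 classes, 10-fold CV
  best C = 2^-5, gamma = 2^-15
  accuracy: mean 1.0000, max fold 1.0000
```

The fit recovers the four planted band-power classes perfectly: each class
boosts one of the θ/α/β/γ bands by 3:1 against unit noise, and the
channel-major AvgPSD features separate them cleanly. On the music side:

```r
ms <- simulate_music(audio_sim_spec(clips_per_class = 6, seed = 2))
v <- extract_music_features(ms$clips[[1]])   # an "anger" clip: 152 BPM, minor
round(v[c("bpm", "bpm_intensity", "mode", "rms")], 3)
```

```
          bpm bpm_intensity          mode           rms
      152.152         0.639         0.008         0.193
```

The estimated tempo matches the generator's 152 BPM profile within a
fraction of a beat; the mode score is near zero because this class also
carries a detuned beating partial that blurs the triad chroma (the clean
minor class, sadness, scores clearly negative). Transition mapping:

```r
mat <- random_transition_matrix(c("fear", "joy"), "joy",
                                after = c("anger", "fear", "joy", "relaxation"),
                                seed = 83)
rec <- simulate_transitions(transition_sim_spec(mat, n_records = 5000, seed = 84))
tt <- transition_probabilities(rec)
head(as.data.frame(tt), 4)
```

```
  before music_type      after count probability
1   fear        joy      anger   240  0.09426551
2   fear        joy       fear   468  0.18381775
3   fear        joy        joy   705  0.27690495
4   fear        joy relaxation  1133  0.44501178
```

Every conditional row sums to 1 and the estimate recovers the generating
matrix to within ~0.011 per cell at this sample size.

A command-line front end covers the same pipelines
(`system.file("exec", "emomap", package = "emomap")` with subcommands
`denoise`, `eeg-features`, `audio-features`, `train`, `rank-channels`,
`transitions`, `synth-eeg`, `synth-audio`, `synth-transitions`).

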