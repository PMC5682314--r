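# mmgesture

Recognising individual finger taps from two-channel mechanomyogram (MMG)
recordings.

When a finger taps, the extensor digitorum muscle in the forearm
contracts and the contraction shakes the skin surface at low frequency
(the dominant MMG band is roughly 10–22 Hz). Two accelerometers on the
muscle belly pick this up as a pair of 1 kHz time series, and because
each finger engages the muscle compartments differently, the burst's
amplitude pattern across the two channels — together with its spectral
signature — identifies which finger moved. Systems built on this idea
drive prosthesis control and post-stroke rehabilitation interfaces,
where the *intent* to move matters more than the motion itself.

`mmgesture` implements the complete recognition pipeline for
motion-intent analysis from such recordings, plus a synthetic-data
generator that reproduces the tapping-protocol structure of a
laboratory acquisition session, so every stage can be validated against
exact ground truth.

## The pipeline

1. **Band-pass preprocessing** — 4th-order Butterworth, 0.1–50 Hz,
   applied forward–backward by default (zero phase, so event boundaries
   are not skewed by group delay).
2. **Tapping-event detection (TED)** — two automatic detectors:
   * *RMS*: a sliding 400 ms root-mean-square envelope
     `g_r[t] = sqrt(mean(x[t..t+W)²))`, thresholded at
     `TH_r = α_r · mean(g_r over a rest interval)` with `α_r = 2.15`;
   * *DTF*: convolution with the 17-tap difference template
     `D = [−1×8, 0, +1×8]`, rectified, thresholded at
     `TH_d = α_d · mean(|g_d| over the rest interval)` with `α_d = 2`.

   Maximal above-threshold runs become events after gap merging and a
   minimum-duration check; detector quality is scored by the false
   detection events ratio `FDER = (N_FP + N_FN) / N_all`.
3. **Feature extraction** — each 1024-sample segment per channel is
   decomposed by a level-5 wavelet-packet transform (db4, periodic);
   the 32 leaves form a 32×32 matrix `X` whose singular values
   `σ_1 ≥ … ≥ σ_32` are the compressed feature vector.
4. **Feature ranking** — each feature is scored by the ratio of its
   between-class spread `d′_ai` (mean absolute pairwise distance of
   class means) to its within-class spread `d_ai` (mean over classes of
   mean absolute pairwise sample distance); the top `k` features per
   channel are kept (default `k = 4`), re-ranked inside every training
   fold.
5. **Classification** — Gaussian naive Bayes, k-nearest neighbours
   (k = 5), or a one-vs-one SVM with the polynomial kernel
   `G(x, z) = (γ·⟨x,z⟩ + coef0)^degree`, `γ = 1`, `coef0 = 0`,
   `degree = 3`, evaluated by stratified 5-fold cross-validation.

## Worked example

```r
library(mmgesture)

# one simulated participant: 5 gestures x 5 reps x 5 rounds at 30 bpm
sim  <- simulate_recording(seed = 1)
filt <- bandpass_filter(sim$recording, filter_spec())

det <- detect_events(filt, detector_spec("rms", recenter = TRUE))
det
#> <detection_result> 125 event(s), threshold(s): 0.1173, 0.1103
compute_fder(det$events, sim$events)$fder
#> [1] 0

# label detected events from ground truth, featurise, cross-validate
fd  <- compute_fder(det$events, sim$events)
lab <- as.character(sim$events$label[fd$matches$truth])
ev  <- event_table(det$events$start_sample, det$events$end_sample, lab)
fz  <- featurize_segments(extract_segments(filt, ev, 1024))
rep <- cross_validate(fz$features, fz$labels, classifier_spec("nbc"),
                      folds = 5, seed = 1, k_per_channel = 4,
                      channel_map = fz$channel_map)
rep$accuracy
#> [1] 0.816
```

The detector recovers all 125 protocol taps with no false detections
(`FDER = 0`), and naive Bayes on the 4 best-ranked singular-value
features per channel identifies the tapping finger in 81.6% of
cross-validated segments (SVM reaches 93.6% on the same features).

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mmgesture", package = "mmgesture"))')
Rscript $CLI simulate --seed 1 --out-signal sig.csv --out-truth truth.csv
Rscript $CLI detect --signal sig.csv --baseline 0:5000 --algorithm rms --out events.csv
Rscript $CLI run --signal sig.csv --truth truth.csv --baseline 0:5000 --seed 1 --out report.json
```

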