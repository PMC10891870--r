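# pigvoc

Recognition of livestock vocalizations from single-channel recordings,
built around a five-class pig call classifier (eating, estrus, howling,
humming, panting). The package is aimed at bioacoustics and precision
livestock-monitoring work where the question is "which behavioral state
produced this sound?", and it implements the full classical
speech-recognition stack in R, end to end:

1. **Kalman-filter enhancement** — each 20 ms frame of the noisy waveform
   is modeled as an AR(p) process `x_k = A x_{k-1} + w_k`, observed as
   `z_k = H x_k + v_k`; the filter alternates prediction
   `x(k|k-1) = A x(k-1|k-1)`, `P(k|k-1) = A P A' + Q` with the gain/update
   `g_k = P(k|k-1) H' / (H P(k|k-1) H' + R)`,
   `x(k|k) = x(k|k-1) + g_k (z_k - H x(k|k-1))`,
   `P(k|k) = (I - g_k H) P(k|k-1)`.
2. **Endpoint detection** — empirical mode decomposition into IMFs,
   Teager energy `psi[n] = x^2(n) - x(n-1) x(n+1)` of the informative IMF
   sum with an adaptive double threshold, refined by short-time cepstral
   distance against a leading-noise reference.
3. **Features** — 39-d MFCCs: pre-emphasis 0.98, 20 ms/10 ms Hamming
   frames, 26 triangular mel filters, DCT-II, 13 static coefficients plus
   regression deltas and delta-deltas; 7-frame context splicing (273-d)
   for the network.
4. **GMM-HMM acoustic models** — one 5-state left-to-right HMM per class
   (`pi = [1, 0, 0, 0, 0]`, self-loop-or-advance transitions), 4-component
   diagonal GMM emissions, trained by multi-sequence Baum-Welch EM
   (40 iterations, tolerance 1e-6), classified by Viterbi score.
5. **Hybrid DNN-HMM** — Viterbi forced alignment of the training clips
   labels each frame with a class-state unit; a 273-128-128-128-25 ReLU
   network with a softmax output is trained on those labels (Adam,
   learning rate 0.003, batch 100, early stopping on a 10% validation
   split); at test time posteriors become scaled likelihoods
   `p(x|q) ∝ p(q|x) / p(q)` and each class is scored by Viterbi in its
   own 5-state trellis.
6. **Evaluation** — confusion matrices with per-class recall
   `TP/(TP+FN)`, specificity `1 - FP/(FP+TN)`, overall accuracy, and
   macro averages.

Because no public corpus of labeled pig calls ships with the package, a
seeded synthetic generator produces five acoustically distinct call
classes (harmonic stacks with class-specific fundamentals, trajectories,
formants and envelopes, embedded in silence plus white and low-frequency
noise at an exact requested SNR) with known labels and boundaries, so
every stage is testable with a known ground truth.

## Worked example

```r
library(pigvoc)

ds  <- generate_dataset(n_per_class = 20, snr_db = 10, seed = 7)
mod <- run_train(ds, include_base = TRUE)   # Base-HMM + GMM-HMM + DNN-HMM
ev  <- run_evaluate(mod, ds)
print(ev)
#> <pigvoc_evaluation>
#>     model accuracy macro_recall macro_specificity
#>  base_hmm        1            1                 1
#>   gmm_hmm        1            1                 1
#>   dnn_hmm        1            1                 1
```

All three systems separate the default five synthetic classes perfectly
at 10 dB SNR (the columns are overall accuracy and the unweighted means
of per-class recall and specificity over the 20 test clips). A single
clip can be classified directly:

```r
clip  <- ds$clips[[ which(ds$manifest$split == "test")[1] ]]
feats <- featurize(clip$audio)                  # T x 39 MFCCs
res   <- decode_hybrid(mod$hybrid, splice_frames(feats, 3))
res$label
#> [1] "eating"
round(res$scores, 1)
#>  eating  estrus howling humming panting
#>   282.4 -1844.5 -1726.3 -1972.4  -859.1
```

The scores are per-class Viterbi log-scores of the prior-scaled network
likelihoods; the margin between the true class and the runner-up is what
the hybrid decoder uses to decide.

The front-end stages are usable on their own: `denoise_signal()` for
Kalman enhancement (`snr_db()` to quantify it), `detect_endpoints()` for
voice-activity segmentation, `compute_mfcc()`/`add_deltas()` for
features, and `init_hmm()`/`baum_welch()`/`viterbi()`/`classify_hmm()`
for the acoustic models. A thin command-line front end over the same
functions is installed at `inst/scripts/pigvoc` with subcommands
`make-fixtures`, `denoise`, `segment`, `featurize`, `train`, `evaluate`
and `classify`.

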