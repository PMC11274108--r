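# msslwear

Estimation of UPDRS-III motor severity scores for Parkinson's disease from
wrist- and ankle-worn gyroscopes recorded during free-living activities.

The UPDRS-III is the clinician-scored motor exam of the Unified Parkinson's
Disease Rating Scale (integer, higher = worse). Its cardinal signs leave
spectral fingerprints in limb-worn gyroscope data — tremor at 4–6 Hz,
bradykinesia as reduced 0.5–3 Hz movement amplitude — which makes continuous,
exam-free severity estimation possible. `msslwear` implements a
**multi-shared-task self-supervised (M-SSL) multichannel CNN-LSTM**:

1. **Preprocessing** — zero-phase band-pass FIR filtering (−3 dB at 0.5 and
   15 Hz), exclusion of exam periods, non-overlapping 5 s windows, and
   per-window spectrograms (1 s Kaiser window, 90% overlap, dB scale).
2. **Self-supervised pretraining** — each unlabeled window spawns three
   transformed copies (random 3-D rotation per sensor site, block
   permutation, smooth time warp); a two-branch CNN (1-D on raw signal,
   2-D on spectrograms) with one shared sigmoid head per task learns to
   recognize each transformation, minimizing
   `L = Σ_t α_t · BCE_t(y_p, P_t)`.
3. **Transfer + fine-tuning** — the convolutional weights move into a
   multichannel CNN-LSTM (one LSTM of size 128 per branch over the
   intra-window sequence, fused by a dense layer of size 256 into a linear
   output); the first convolutional blocks are frozen and the rest trains
   under the Huber loss (δ = 1) with Adam.
4. **Evaluation** — leave-one-subject-out or grouped k-fold splits with a
   strict no-leakage audit; window estimates averaged per assessment round;
   Pearson r, R², MAE, RMSE, with activity and medication-state breakdowns.
5. **Simulation** — a synthetic Parkinson's cohort generator (two protocol
   groups, OFF→ON medication trajectories, severity-dependent tremor and
   bradykinesia) that emits the same CSV+JSON interchange format the
   pipeline reads, so everything is testable without clinical data.

The network engine (convolutions, LSTM, pooling, Adam, backpropagation) is
implemented in the package itself — vectorized R over compiled
RcppArmadillo convolution kernels — and its gradients are verified against
finite differences in the test suite.

## Worked example

Simulate a small cohort, preprocess it, and cross-validate the
self-supervised model:

```r
library(msslwear)

cohort <- simulate_cohort(cohort_config(n_subjects = 8, group_a_fraction = 1,
                                        round_duration_s = 60, exam_s = 10,
                                        seed = 21))
stft <- stft_config(crop_hz = 16)           # keep 0–16 Hz (filter passband + guard)
ws <- preprocess_cohort(cohort, stft = stft)

net  <- network_config(r_filters1 = 8, r_filters2 = 16, s_filters1 = 8,
                       s_filters2 = 16, task_head = 32, lstm = 16, fusion = 32)
tcfg <- train_config(epochs = 25, learning_rate = 3e-3, seed = 7)
folds <- grouped_folds(unique(ws$meta$subject), 3, seed = 7)

res <- run_experiment(ws, "mssl_cnn_multi_lstm", folds, net, tcfg,
                      stft = stft, pretrain_epochs = 15)
print(res$pooled)
#> rounds: 32  r = 0.737 (p = 1.51e-06)  R2 = 0.363  MAE = 5.35  RMSE = 7.51
```

Each of the 32 held-out assessment rounds gets one estimate (the mean of
its 5 s window estimates); `r` is the Pearson correlation between those
estimates and the true planted severities, `MAE` their mean absolute error
on the UPDRS scale. A linear read-out of 4–6 Hz band power alone reaches
r ≈ 0.9 on this generator — the deep models must at least rediscover that
structure through the self-supervised route (pretrain → transfer → freeze →
fine-tune) to pass the test suite.

The same pipeline runs from a shell:

```sh
Rscript -e 'msslwear::run_cli(commandArgs(TRUE))' simulate \
    --n-subjects 8 --seed 21 --round-s 60 --out-dir cohort/
Rscript -e 'msslwear::run_cli(commandArgs(TRUE))' evaluate \
    --data-dir cohort/ --out-dir results/ --variant mssl_cnn_multi_lstm --seed 7
Rscript -e 'msslwear::run_cli(commandArgs(TRUE))' benchmark \
    --data-dir cohort/ --out-dir results/ --seed 7   # all 7 model variants
```

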