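# sulfsite

Sequence-based prediction of **cysteine S-sulfhydration (persulfidation)
sites**. S-sulfhydration converts a cysteine thiol (–SH) to a persulfide
(–SSH) and is a key signaling modification in cardiovascular and
neurological biology. Experiments can confirm a modified cysteine but
cannot certify an unmodified one, so training data carry label noise in
the negative class — a problem this package addresses head-on.

`sulfsite` is aimed at computational biologists who have (or can
simulate) a set of proteins with annotated cysteine sites and want a
self-contained, CPU-trainable site classifier with honest evaluation
machinery.

## The model

Each candidate site is a `2k + 1` residue window centered on the
cysteine (default a 31-mer, `-15 C +15`; termini padded with `-`). The
pipeline has four stages:

1. **Entropy-weighted transformer encoder.** A masked-language-model
   (MLM) transformer (per layer: multi-head self-attention and
   `FFN(x) = max(0, xW₁ + b₁)W₂ + b₂`, each as
   `LayerNorm(x + Sublayer(x))`) is pretrained on the window sequences
   (15% of tokens masked; 80/10/10 mask/keep/random split). Instead of
   using only the last layer, every layer's output `Xᵢ` is scored by its
   mean positional Shannon entropy `H(Xᵢ)` under the tied MLM head, and
   the embedding is the weighted sum `L = Σᵢ wᵢXᵢ` with
   `wᵢ = H(Xᵢ)/Σⱼ H(Xⱼ)`.
2. **Confident learning.** Out-of-fold class probabilities `P[i][j]`
   from cross-validated classifiers give per-class self-confidence
   thresholds `tⱼ = mean{ P[i][j] : ỹᵢ = j }`; a negative whose
   `P[i][0]` falls strictly below `t₀` is flagged as a probable hidden
   positive and removed.
3. **Directional multi-GRU.** The window is split into left (`-k..0`),
   right (`0..+k`) and full parts, oriented by a 3-letter direction code
   over `{L, R}` (default `RLL`), and fed to three independent GRUs
   whose gates follow
   `z_t = σ(W⁽ᶻ⁾L_t + U⁽ᶻ⁾M_{t-1})`, `r_t = σ(W⁽ʳ⁾L_t + U⁽ʳ⁾M_{t-1})`,
   `M̃_t = tanh(W⁽ᵐ⁾L_t + r_t ⊙ U⁽ᵐ⁾M_{t-1})`,
   `M_t = z_t ⊙ M_{t-1} + (1 − z_t) ⊙ M̃_t`.
4. **Attention + CNN + sigmoid head.** The concatenated branch outputs
   pass through multi-head self-attention; GRU and attention features
   are fused and refined by a 1-D CNN (kernel 2, 3 layers with
   max-pooling), then a two-layer fully connected head with dropout 0.5
   and a sigmoid emits the site probability.

Evaluation reports Sn, Sp, Pre, Acc, MCC and AUC (Mann–Whitney), with
protein-grouped stratified cross-validation so no protein leaks across
folds. A planted-motif synthetic generator (A/K/R/V enriched near the
center of positive windows, enrichment decaying outward, configurable
label noise) makes every stage testable without downloads. All network
forward/backward passes are implemented in the package (R matrix algebra
with the GRU recurrence and attention scores in compiled code) — no
deep-learning framework is required.

## Worked example

```r
library(sulfsite)

# a labeled synthetic window set: 200 modified + 600 unmodified cysteines
d <- generate_synth(synth_config(n_pos = 200, n_neg = 600, k = 7), seed = 42)
split <- split_by_protein(d, test_fraction = 0.2, seed = 42)

cfg <- model_config(k = 7, gru_hidden = 48, gru_layers = 2, n_heads = 2,
                    cnn_layers = 2, filters = 16, fc_hidden = 32,
                    mlm = list(epochs = 2),
                    train = list(epochs = 12, batch_size = 64))
fit <- sulf_fit(split$train, cfg, seed = 1)
fit
#> S-sulfhydration site classifier
#>   direction RLL | window 2*7+1 | encoder 4 x 64 | GRU 2 x 48
#>   trained on 548 windows (92 validation), best epoch 12
#>   validation: Acc 0.891 | MCC 0.710 | AUC 0.932

pred <- predict(fit, split$test)
evaluate_predictions(pred$probability, split$test$label)
#> # A tibble: 1 × 6
#>      Sn    Sp   Pre   Acc   MCC   AUC
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 0.775 0.908 0.738 0.875 0.672 0.929
```

The fit prints the training geometry and its validation panel; the
prediction tibble has one row per window (`protein_id`, `position`,
`probability`, `predicted`), and `evaluate_predictions()` computes the
six-metric panel at threshold 0.5 — here the model recovers the planted
motif with held-out AUC ≈ 0.93 in under a minute on one CPU.
`tidy(fit)` returns the per-epoch loss log, `glance(fit)` a one-row
summary, and `autoplot(fit)` the training curves. Real data enter the
same way via `read_fasta()`, `read_site_table()` and
`extract_windows()`; `direction_sweep()` compares all eight reading
orientations, and `confident_filter()` audits the negative class before
a final fit.

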