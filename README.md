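# spasmfusion

Detection of epileptic spasms in infants (infantile epileptic spasms
syndrome / West syndrome) from **synchronized multichannel EEG and surface
EMG**. The package implements a dual-stream neural detector together with
the complete study protocol around it — preprocessing, dense ictal
windowing, class balancing, subject-wise splits, Adam training with early
stopping, and sensitivity/specificity/ROC evaluation — plus a seeded
synthetic cohort generator that stands in for proprietary clinical
recordings.

It is written for researchers in clinical neurophysiology and biosignal
machine learning who want a fully inspectable, oracle-tested reference
implementation of this architecture family in R: every forward **and**
backward pass is authored here (R with small C++ kernels for the sequential
recurrences and convolutions) and checked against independent naive oracles
and finite differences in the test suite.

## The model

For a 1-s window with EEG `x ∈ R^{25×T}` and EMG `x ∈ R^{4×T}`, each
modality is encoded by:

1. **CWT band scalogram** — complex Morlet wavelet
   `ψ(t) = π^{-1/4} e^{iω₀t} e^{-t²/2}` (ω₀ = 6), coefficient magnitudes
   averaged over 8 log-spaced scales per physiological band
   (EEG: δ 1–4, θ–α 4–13, β 13–30, γ 30–70 Hz), giving `F×C×T` with F = 4.
2. **ST-Conv** — temporal conv (1×25, 4→16) and spatial conv across
   electrodes (13×1 EEG / 3×1 EMG, 16→4), each BN + LeakyReLU, plus a 1×1
   residual; 4,384 learnable parameters over both blocks.
3. **Bi-Mamba** — the flattened `T×D` sequence (D = 4C) is expanded to two
   streams of width `E = 2D`; per stream a causal depthwise conv + SiLU
   produces input-dependent SSM parameters `Δ_t, B_t, C_t` (N = 32), which
   drive the zero-order-hold discretized diagonal scan
   `h_t = exp(Δ_t A) h_{t-1} + (exp(Δ_t A)−I)A^{-1}B_t u_t`,
   `y_t = C_t h_t + D u_t` with fixed `A = −diag(1..N)`; the backward
   stream runs time-reversed, both are SiLU-gated, summed, projected.

The two encoded sequences (projected to a common width 128) are fused by
**Cross Time-Mixing** — linear recurrent cross-modal attention in both
conditioning directions: token-shifted receptance from the query stream,
token-shifted key/value from the other modality, and the channel-wise
weighted key-value recurrence

    s_t = e^{-ω} s_{t-1} + e^{k_t},   p_t = e^{-ω} p_{t-1} + e^{k_t} v_t,
    wkv_t = (p_{t-1} + e^{u+k_t} v_t) / (s_{t-1} + e^{u+k_t}),

gated by `σ(r_t)` and projected (230,400 parameters at width 128). A pooled
two-layer MLP head yields the spasm / non-spasm logits. Both the Bi-Mamba
scan and the WKV recurrence are strictly linear in `T`.

## Worked example

Simulate a desk-scale cohort (10 subjects, 60-s recordings at 256 Hz),
run the full pipeline, and train the fused detector:

```r
library(spasmfusion)

synth <- synth_preset("desk")                  # seeded synthetic cohort
mcfg  <- model_config(fs = 256)                # reference architecture
data  <- prepare_experiment_data(synth, mcfg)  # filter/window/balance/split

count_parameters(build_model(mcfg, seed = 1))
#> # A tibble: 10 x 2
#>    module            params
#>    <chr>              <int>
#>  1 cwt                    0
#>  2 stconv_eeg          2512
#>  3 stconv_emg          1872
#>  4 bimamba_eeg       248400
#>  5 bimamba_emg        10176
#>  6 proj_eeg           12928
#>  7 proj_emg            2176
#>  8 cross_time_mixing 230400
#>  9 classifier          8386
#> 10 total             516850

fit <- train(build_model(mcfg, seed = 101), data$train, data$val,
             train_preset_desk(n_runs = 1))
evaluate_model(fit$model, data$test)
```

On this synthetic cohort the fused EEG+EMG model clearly beats the
EMG-only ablation (`model_config(fs = 256, fusion = "none_emg_only")`) -
motion artifacts in the generator make muscle bursts an ambiguous witness
of a spasm, so the modality ordering of the clinical study is reproduced
qualitatively. The five-seed experiment
(`run_experiment(data, variants, train_preset_desk())`) printed:

```
  variant  acc_mean acc_sd spe_mean spe_sd sen_mean sen_sd auc_mean  auc_sd
1 emg_only     80.9    0      100      0       61.8   0       0.718 0.0329
2 fused        91.8   10.4     85.3   22.1     98.2   1.61    0.995 0.00519
```

The parameter table is exact: the two ST-Conv blocks total 4.4 K learnable
parameters, the fusion module 0.23 M, the EEG-stream bidirectional
state-space block 0.25 M, and the scalogram front end has none.

`autoplot()` methods exist for scalograms, training histories
(`tidy(fit)` / `glance(fit)` give the broom-style views) and ROC curves
(`roc_auc(labels, scores)`).

A thin command-line wrapper ships in `inst/cli/spasmfusion`
(`simulate`, `profile`, `train`, `eval` subcommands).

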