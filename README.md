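# modswarn

Real-time, multi-horizon early warning of **multiple organ dysfunction
syndrome (MODS)** for trauma sepsis ICU patients.

MODS — SOFA sub-scores of 2 or more in at least two organ systems — is the
complication that drives most sepsis deaths, and trauma sepsis patients are
a distinct, under-studied subgroup. Bedside scores such as SOFA describe the
*current* state; they do not forecast deterioration. `modswarn` implements a
forecasting workflow: at every evaluation hour `t_k` the model reads only
the observation window `(t_k − 4 h, t_k]` and predicts whether MODS onset
`T_MODS` will fall in `(t_k, t_k + h]` for `h ∈ {6, 12, 24}` hours,

```
y_h(t_k) = 1  iff  t_k < T_MODS ≤ t_k + h,
```

with windows where MODS is already present (`T_MODS ≤ t_k`) excluded to
prevent label leakage.

The model is a **frequency-separated dual-stream network**: the seven
continuously monitored vitals (SBP, DBP, MBP, heart rate, temperature,
SpO2, respiratory rate) form a 4-step hourly sequence consumed by a
recurrent (LSTM) stream, while the 34 sparsely sampled features (labs, GCS,
drug doses, demographics) feed a feed-forward stream; the two are
concatenated into a batch-normalized trunk. The network is **pre-trained on
30-day mortality** in a large general-ICU pool (trauma sepsis excluded),
then all parameters are transferred as initialization and **fine-tuned** on
the trauma sepsis cohort with a three-logit head, minimizing the average
binary cross-entropy across the three horizons. Evaluation uses
**patient-level bootstrap** confidence intervals (patients resampled with
replacement, records weighted by selection counts), calibration curves with
Brier scores, clinical threshold tables (10/20/30 %), learning curves, and
Shapley-value attributions with exact additivity.

Real MIMIC-IV / eICU extracts are credentialed and out of scope; the
package ships a **synthetic ICU simulator** in which one latent severity
process drives vitals, labs, SOFA deterioration (hence MODS) and mortality,
so the entire pipeline — including the transfer-learning benefit — runs
offline.

## Worked example

```r
library(modswarn)

# a small synthetic benchmark: general-ICU pool + trauma sepsis cohort
bench <- transfer_benchmark(pool_n = 300, cohort_n = 150, seed = 5)
prep  <- prepare_benchmark_data(bench, seed = 5)
nrow(prep$cohort$stays)            # stays surviving the inclusion filter
#> [1] 106

# pre-train on 30-day mortality, transfer, fine-tune on MODS
fit <- fit_variant(variant_spec("PT-MLP.LSTM-eICU"), prep$mods, prep$pool,
                   config = desk_finetune_config(5),
                   pretrain_config = desk_pretrain_config(5),
                   head_config = desk_head_config(5),
                   sizes = desk_net_sizes(), seed = 5)

probs <- predict_risks(fit, prep$mods$test)
round(head(probs, 3), 4)       # one risk per horizon at every evaluation hour
#>          y6    y12    y24
#> [1,] 0.0222 0.0519 0.1232
#> [2,] 0.0223 0.0509 0.1200
#> [3,] 0.0197 0.0441 0.1061

compute_auc(probs[, "y6"], prep$mods$test$y[, "y6"])
#> [1] 0.8233632                   # 6-h discrimination on held-out patients

rep <- metric_report(probs, prep$mods$test$y, prep$mods$test$meta$stay_id,
                     bootstrap_config(B = 200, seed = 1))
```

The three probabilities are this patient-hour's risk of developing MODS
within the next 6, 12 and 24 hours; they rise with the horizon because the
prediction windows are nested. The AUC is computed on held-out *patients*
(never windows of patients seen in training).

Single components work standalone:

```r
sofa_subscore("coagulation", 141)   # platelets 141 K/uL -> sub-score 1
assign_mods_labels(t_k = 33, t_mods_h = 37)   # y6 = y12 = y24 = 1
```

## Package layout

- `R/registry.R`, `R/cohort.R` — feature registry, cohort container, CSV
  I/O, inclusion filters
- `R/sofa.R` — hourly six-organ SOFA scoring, Sepsis-3 and MODS detection
- `R/labeler.R` — window extraction and multi-horizon labeling
- `R/preprocess.R` — clipping, imputation, Z-scoring, frequency split
- `R/nnet.R`, `R/model.R` — the dual-stream network, training protocol,
  transfer, ablation variants
- `R/evaluate.R` — bootstrap CIs, calibration, thresholds, learning curves
- `R/shap.R` — Shapley attributions and reports
- `R/simulate.R` — the synthetic ICU generator
- `vignettes/modswarn-methods.Rmd` — the methods vignette
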