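# surgrsd

Intra-operative **Remaining Surgery Duration (RSD)** prediction for
endoscopic pituitary surgery, from per-second surgical-workflow annotations
and per-frame features.

Anaesthetists use RSD estimates in the closing phase of a surgery — to
titrate anaesthetic agents down for a prompt wake-up, to time pain relief,
and to call for the next patient — so accuracy in the **last 10–20 minutes**
matters most. Pituitary surgery (the endoscopic transsphenoidal approach,
eTSA) makes this hard: of its 14 annotated workflow steps only 8 are
mandatory, optional steps come and go, haemostasis can recur anywhere, and
total durations are long-tailed. `surgrsd` implements, end to end, a ladder
of predictors for this setting together with a calibrated workflow
simulator and an evaluation harness, so every method is trainable and
comparable at desk scale without access to surgical video.

## The methods

With `T` the (unknown) total duration, `t_el` the elapsed time and
`t_rsd = T − t_el` the target, all in minutes:

* **Naive** — `t_rsd = max(0, T_ref − t_el)` with `T_ref` the mean full
  duration of the training split.
* **Step-inferred** — steps are assumed sequential with reference durations
  `t_ref_s` (training means):
  `t_rsd = max(0, t_ref_s − t_el_s) + Σ_{i>s} t_ref_i`.
  Its sequential assumption is knowingly violated by pituitary workflows;
  it is the documented weak baseline.
* **Sequence matching (k-NN)** — the run-length-compressed elapsed step
  sequence is compared by **Levenshtein distance** with each historical
  surgery's sequence truncated at the same timestamp; `T_ref` is the mean
  full duration of the `k = 3` nearest neighbours (optionally adding an
  instrument-sequence distance as an unweighted sum).
* **Temporal multi-task network** — a two-layer LSTM over per-second frame
  features that jointly predicts the current step (weighted cross-entropy)
  and the normalized RSD (Smooth L1 on `t_rsd / 10`), with the input at
  second `t` optionally augmented by **prior-step context**:
  `l_t = f(I_t) ⊕ s_{t−1}`, where `s_{t−1}` concatenates the previous
  second's step probabilities and their mean over the last `t̂` seconds.
  The four ablation variants (`rsd`, `s_rsd`, `si_rsd`, `full`) toggle the
  step head, the instrument head and the context input.

Evaluation follows the field's convention: MAE per video over the full
duration and the last 20/10 minutes, mean-averaged over videos, macro-F1
for step recognition, and paired Wilcoxon signed-rank tests between
methods.

## Worked example

```r
library(surgrsd)

cohort <- sample_cohort(sim_config(), n_train = 60, n_val = 0, n_test = 10, seed = 7)

naive    <- fit_rsd_naive(cohort)
step     <- fit_rsd_step_inferred(cohort)
seqmatch <- fit_rsd_seqmatch(cohort, k = 3)

predictions <- list(
  naive         = predict(naive, cohort, split = "test"),
  step_inferred = predict(step, cohort, split = "test"),
  seqmatch      = predict(seqmatch, cohort, split = "test")
)
head(predictions$seqmatch, 3)
#> # A tibble: 3 × 3
#>   video_id   sec rsd_pred_min
#>   <chr>    <int>        <dbl>
#> 1 sim_061      0         58.3
#> 2 sim_061      1         58.2
#> 3 sim_061      2         58.2

report <- evaluate_rsd(predictions, cohort)
report
#> <rsd_eval>
#> # A tibble: 3 × 4
#>   method        full            last10         last20
#>   <chr>         <chr>           <chr>          <chr>
#> 1 naive         22.29 +/- 14.49 8.48 +/- 5.27  11.08 +/- 3.73
#> 2 seqmatch      17.32 +/- 11.71 4.79 +/- 2.16  7.62 +/- 3.35
#> 3 step_inferred 17.70 +/- 7.32  10.96 +/- 4.88 10.28 +/- 4.71
```

Each row is the mean ± sd over the 10 test surgeries of per-video MAE in
minutes; sequence matching roughly halves the last-10/last-20 error of both
baselines, because truncating historical sequences at the same timestamp
lets it recognise whether the ongoing surgery is pacing like a short or a
long one. `report$comparisons` holds the paired signed-rank p-values, and
`autoplot(report)` / `plot_rsd_series(predictions, cohort, "sim_061")` draw
the summary and the per-second prediction traces.

The temporal model runs the same way once frame features exist
(`sample_cohort_features()` attaches synthetic encoder embeddings):

```r
cohort <- sample_cohort_features(cohort, embedding_config(dim = 16), seed = 8)
cfg    <- temporal_config(feature_dim = 16, n_steps = 14, variant = "full",
                          hidden_size = 64, epochs = 16)
model  <- fit_rsd_temporal(cohort, cfg)
predict(model, cohort, split = "test")   # rsd_pred_min + step_pred per second
```

`run_experiment()` (or the `inst/cli/surgrsd.R` script, with subcommands
`simulate`, `predict`, `train`, `evaluate`, `compare`, `run`) wires
simulate → fit → predict → evaluate from a single YAML/list configuration.

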