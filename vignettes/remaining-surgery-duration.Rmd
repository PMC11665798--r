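---
title: "Predicting remaining surgery duration from workflow sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting remaining surgery duration from workflow sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgrsd)
```

## The problem

During endoscopic transsphenoidal pituitary surgery (eTSA), the remaining
surgery duration (RSD) at elapsed time $t_{el}$ is $t_{rsd} = T - t_{el}$,
where the total duration $T$ is unknown until the surgery ends. An online
predictor must therefore estimate $t_{rsd}$ every second from what has been
observed so far. The clinically useful window is the last 10–20 minutes,
when anaesthetists act on the estimate.

What makes eTSA workflows hard is their variability: of the 14 annotated
steps, 8 are mandatory ("core") and 6 optional; haemostasis can recur after
any step; step order varies between surgeons; and total durations are
long-tailed. A predictor that only knows the average surgery is badly wrong
exactly on the cases where a good estimate matters most.

`surgrsd` represents one surgery as a `workflow_timeline`: step intervals
on a 1 Hz integer-second grid, half-open `[start, end)`, contiguous and
covering `[0, T)` exactly. The 1 Hz grid matches the 1-frame-per-second
sampling convention of surgical video analysis and avoids double counting
at boundaries. RSD is reported in minutes; internal time is in seconds.

### Prediction-time convention

The prediction at second $t$ may use the frames observed at seconds
$0..t$ — equivalently, the step intervals with `start_sec <= t` — and the
elapsed time is $t$ seconds, matching the ground truth
$t_{rsd}(t) = (T - t)/60$. This convention is what makes two structural
properties hold exactly: a query identical to a training surgery is its own
unique nearest neighbour from the very first second (the first step label
is already observed at $t = 0$), and the sequence-matching estimator with
$k$ equal to the full history size collapses bit-for-bit onto the naive
estimator.

## The statistical ladder

**Naive.** $T_{ref}$ is the arithmetic mean of the training surgeries'
full durations and $\hat t_{rsd} = \max(0, T_{ref} - t_{el})$. It is exact
when every surgery is identical and is the anchor all other methods are
compared against.

**Step-inferred.** Each step gets a reference duration (mean total time
spent in that step across the training surgeries that contain it) and the
steps are placed in a canonical order. The estimate adds the unfinished
part of the current step to the reference durations of all later canonical
steps. Two conventions are needed because pituitary workflows violate the
method's sequential assumption:

* *Canonical order*: steps are ranked by their mean normalized
  first-occurrence time (first start divided by $T$, averaged over training
  surgeries containing the step). Steps absent from training are excluded.
* *Elapsed time in step*: the time already spent in the current step's
  label (pooled across repeats), so a recurring haemostasis keeps drawing
  down a single reference duration.
* *Unseen step at inference*: the estimator falls back to the sum of
  reference durations after the last known canonical position — graceful
  degradation rather than an error, since optional steps routinely appear
  in test surgeries only.

These conventions keep the baseline faithful, including its known failure
mode: it cannot react to workflow variability, which is the gap the
sequence-matching estimator closes.

**Sequence matching.** At each second the query's elapsed step sequence is
run-length compressed (collapsing each interval to one symbol — the
"compression" that keeps edit distances cheap) and compared by Levenshtein
distance to every historical surgery's compressed sequence *truncated at
the same elapsed time*. Histories that have already finished
($T_i < t_{el}$) contribute their full sequence. The $k$ nearest histories
(default $k = 3$) vote with their mean full duration. With instrument
annotations enabled, the instrument-sequence distance is added as an
unweighted sum. Distance ties are broken deterministically by
`(distance, |T_i − median training duration|, training index)`: the
median-proximity key biases ties toward typical surgeries and the index
makes the estimator reproducible.

Because distances only change when a new interval starts (in the query, or
in a history that is still running), the per-second series is computed on
that event grid and held piecewise in between; within a segment the
prediction decays linearly as $\max(0, T_{ref} - t_{el})$.

## The temporal multi-task model

The learned model is a two-layer LSTM (hidden size configurable, default
128) over per-second feature vectors from any frozen frame encoder, with up
to three heads:

* a step-classification head trained with weighted cross-entropy, class
  weights $w_c = N / (S_{present} \cdot n_c)$ so that balanced classes get
  weight 1 and classes unseen in training are excluded;
* an optional instrument head (same loss form);
* an RSD regression head trained with Smooth L1
  ($0.5 r^2/\beta$ for $|r| < \beta$, else $|r| - \beta/2$, default
  $\beta = 1$) on RSD **normalized by dividing by 10 minutes**, which keeps
  the regression loss on the same scale as the classification losses. The
  training log records the realized classification-to-regression loss
  ratio as a diagnostic; the task losses themselves are summed unweighted
  (multipliers exposed for ablations).

The input at second $t$ concatenates the frame feature, the elapsed time
as a single scalar normalized by 3600 s (an image-channel encoding of time
does not transfer to a feature-vector interface; one $O(1)$ scalar carries
the same information), and — in the `full` variant — the prior-step
context: the previous second's step-probability vector plus the mean over
the last $\hat t$ seconds (default 30 s, configurable). At $t = 0$ both
probability blocks are uniform, the only probability-valid uninformative
cold start.

Training choices, all of which were genuinely open:

* **Teacher-free unrolling**: context features are built from the model's
  own running predictions during training, exactly as at inference, so
  there is no train/test mismatch. Gradients are stopped at the context
  input (the probabilities are treated as data); backpropagating through
  the feedback path would couple every timestep to every earlier one at
  substantial cost for no clear benefit at this scale.
* **Truncated BPTT** with a configurable window (default 512 s) bounds
  memory on hour-long videos; state (and the context buffer) carries
  across chunk boundaries, only gradients are cut.
* **Optimizer**: Adam, one surgery per update, per-video losses averaged
  over time so that long surgeries do not dominate by frame count. The
  learning-rate schedule defaults to 1e-3 for the first half of the epochs
  and 1e-4 for the second (40 epochs in the reference configuration).
* **Initialization**: uniform $\pm 1/\sqrt{H}$ with forget-gate biases at
  1 (the standard trick that lets memory survive early training);
  initialization and epoch shuffling derive from the config seed, so
  training is bit-reproducible on one CPU.
* **Checkpoint selection**: lowest validation full-duration RSD MAE; the
  final weights are used when no validation split exists.

Inference (`predict()`) is strictly causal — the output at second $t$ is a
function of frames $0..t$ only — and the test suite enforces this with
randomized future-frame perturbation trials. Reported RSD is denormalized
to minutes and clamped at zero, matching the non-negativity of the target.

## The workflow simulator

Real eTSA video data are not distributable, so the simulator is a
first-class module: it generates cohorts with the structural features the
predictors are supposed to exploit, calibrated to published cohort-level
statistics.

One draw proceeds: pick a duration archetype (a global multiplier, default
mixture $\{1.0: 0.75,\ 1.6: 0.25\}$); include each optional step with its
probability (default 0.5); transpose adjacent core steps with probability
0.1; insert haemostasis instances after steps with probability 0.12 each,
plus one guaranteed instance after tumour excision (haemostasis is core);
draw each interval's duration from a per-step log-normal (log-sd 0.55,
positive and right-skewed — the natural family for durations) scaled by the
archetype multiplier, rounded to at least 1 s.

The per-step mean durations were fixed a priori from surgical plausibility
and only the global `duration_scale` was calibrated (to 0.90) so that
simulated total durations reproduce the published cohort profile —
median ≈ 64 min, IQR ≈ 53–84 min, with mean > median (heavy right tail).
The test suite re-checks this distribution on 5000 draws at ±10%.

Two deliberate hooks give sequence-aware methods signal to exploit:

* the *archetype marker*: one early optional step (default turbinate
  lateralisation) whose inclusion probability differs by archetype
  (defaults 0.9 long / 0.15 short), so the step sequence carries an early
  cue of a long surgery;
* *embedding alias groups*: the synthetic frame-feature generator (step
  centroid + isotropic Gaussian noise, standing in for any frozen encoder)
  can give several steps one shared centroid, emulating phases that look
  alike on camera and are only distinguishable from workflow history.

What the simulator does **not** emulate: appearance (there are no images,
only centroid embeddings), surgeon identity effects, instrument-step
correlations beyond a per-step preference pool, or within-step
non-stationarity. Tests passing on simulated cohorts therefore demonstrate
the estimators' structural correctness and relative ordering under the
stated workflow assumptions — not clinical-grade error levels on real
video.

## Evaluation harness

MAE is computed per video (so surgeries weigh equally regardless of
length) over three windows — full duration, last 20 min, last 10 min
(`[max(0, T − 60K), T)`; shorter videos use their full duration) — then
mean-averaged with a sample sd across videos. Step recognition is scored
with macro-F1 over the classes present in the ground truth (truth-absent
classes are excluded to avoid 0/0; an unpredicted class contributes
precision 0). Method pairs are compared with the two-sided paired Wilcoxon
signed-rank test: zero differences are dropped; for fewer than 26 non-zero
pairs the p-value comes from the exact null distribution built by
convolution over the observed (possibly tied) ranks, otherwise from the
normal approximation with tie correction. The exact-by-convolution route
matches `psignrank` when there are no ties and stays valid under ties,
where the textbook tables do not apply.

## Problem sizes used by the test suite

The package's own benchmarks are sized for a single CPU: the statistical
comparison uses 60 training / 20 test simulated surgeries at full length;
the temporal learning benchmark uses 5 always-core steps, 16-dimensional
embeddings at noise sd 0.05, 40/5/10 surgeries of a few minutes each, and
10 epochs at hidden size 32; the context-utility benchmark uses the full
14-step vocabulary at `duration_scale = 0.09`, noise sd 0.4 with aliased
closure steps, a strong early marker (inclusion 1.0/0.0 by archetype,
multiplier 2.0), 40/4/10 surgeries and 16 epochs, averaged over five
seeds. The context comparison needs this larger training budget: with
fewer videos or epochs the context input — built from the model's own,
initially poor, predictions — acts as noise and the no-context variant
wins, the same small-data behaviour reported for the smaller of the two
published cohorts.

## Known limitations

* The step-inferred canonicalization is a modelling choice layered on a
  method whose assumptions the domain violates; it is included as the
  honest baseline, not as a recommendation.
* Sequence matching treats all steps as equally costly to edit; weighted
  or time-warped distances are out of scope.
* The temporal model's determinism claim holds for this single-threaded
  CPU implementation; multi-threaded BLAS backends may reorder floating
  point reductions.
* Hour-long surgeries at 1 Hz make the per-update sequences thousands of
  steps long; the default truncation window (512 s) trades gradient
  horizon for memory, and context beyond the window must survive through
  the LSTM state.
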