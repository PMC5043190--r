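---
title: "Methods: the memovie simulation and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the memovie simulation and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

memovie models an old/new recognition memory experiment on movie shots.
Subjects watch one episode of a series; later, across sessions spanning
minutes to a year, they are shown individual shots — *targets* from the
watched episode and matched *foils* from an unwatched episode — and answer
"old" or "new". The package provides a generative simulator for such data
and the complete analysis pipeline: exclusion rules, signal-detection
metrics, response-consistency tests, per-property content statistics, and
content-based prediction of memorability with behavioral upper bounds.

This vignette documents the model, its parameters, what the generator does
and does not try to capture, and the numerical choices baked into the
analyses.

## The generative model

Each episode is tiled by `n_shots_per_episode` shots with durations (in
frames) drawn log-uniformly on [1, 90], matching the heavy skew of real
shot-length distributions. Every shot receives a content annotation: binary
flags (action, indoor, depicted emotion, elicited emotion), per-identity
character flags with dependent viewpoint flags (a viewpoint can only be
marked when its character is present), sound and emotion and object
inventories, derived counts, and continuous covariates (contrast, color
content, sound level).

Foils are matched to targets by minimizing the Hamming distance over
character/viewpoint bits (ties broken by duration difference, then id)
under a global greedy assignment, mimicking matched-stimulus designs.

A subject's probability of answering a trial correctly is logistic:

$$
\mathrm{logit}(p) \;=\; \beta^\top x \;+\; \gamma \log(n_\text{frames})
\;-\; \delta \log(1 + \text{days}) \;+\; a_s \;+\; b\,[\text{foil}]
\;+\; m_{\text{manipulation}},
$$

clipped to `prob_floor_ceiling` (default [0.02, 0.98]) so that no trial is
deterministic. $x$ is the shot's content vector restricted to the features
named in `true_weights`; $a_s \sim N(0, \texttt{subject\_ability\_sd}^2)$
is a stable per-subject ability; $b$ (`foil_bias`) allows asymmetric
target/foil difficulty; $m$ is a per-manipulation offset (e.g. occlusion,
sound removal). Single-frame presentations drop the duration term.
Responses are then single Bernoulli draws, which makes every downstream
null model exact by construction.

Trial schedules place both members of a target/foil pair in the same
session, so every session — and hence any subset of sessions — is exactly
balanced. Sessions sit at nominal days 0, 1, 7, 30, 90, 365 with elapsed
times drawn uniformly from realistic windows (0–1 h, 22–26 h, 6–8 d,
27–33 d, 85–95 d, 335–395 d). A fraction of trials (default 3%, split
evenly between targets and foils) are repeats of earlier shots, scheduled
into later sessions; these power the self-consistency analyses.

All randomness derives from one integer seed through named substreams
(shots, annotations, schedule, responses, abilities, foils), so changing
e.g. the response draw does not perturb the stimuli.

## Parameters

| Parameter | Default | Role |
|---|---|---|
| `n_subjects` | 20 | simulated participants |
| `n_shots_per_episode` | 300 | shots per episode |
| `n_characters` / `n_sounds` / `n_emotions` / `n_objects` | 29 / 13 / 20 / 25 | annotation inventory sizes |
| `true_weights` | small named set | content weights $\beta$ (features not named get 0) |
| `duration_weight` | 0.35 | $\gamma$, effect of log shot duration |
| `retention_rate` | 0.25 | $\delta$, forgetting per log-day |
| `subject_ability_sd` | 0.5 | SD of stable subject ability |
| `foil_bias` | 0 | target/foil asymmetry |
| `manipulation_offsets` | per type | difficulty shift per presentation manipulation |
| `session_days` | 0,1,7,30,90,365 | nominal retention intervals |
| `repeat_fraction` | 0.03 | fraction of repeat trials |
| `prob_floor_ceiling` | 0.02, 0.98 | clipping of $p$ |
| `seed` | 1 | master RNG seed |

Defaults were chosen so that a default dataset lands in the
empirically plausible regime of human performance on this task: overall
percent correct in the high 70s to mid 80s, visible forgetting over a year,
and per-subject spread of a few percent.

## What the generator is, and is not

It is a *statistical twin* of the experiment: correct marginal task
structure (balance, sessions, repeats, exclusions all operate exactly as on
real data), content-driven and duration-driven difficulty shared across
subjects, stable individual differences, and forgetting. This is enough to
validate every estimator and null model in the package.

It is not a model of memory. Conditional on the shot's features, the
elapsed time, and the subject's ability, responses are independent
Bernoulli draws — there are no encoding-state fluctuations, no
interference between similar shots, no response-time dynamics, no
criterion drift within a session. Consequently the simulator reproduces
independence nulls *exactly*, which is a feature for testing (observed
consistency must match the analytic null) but means effect sizes of real
human consistency above the null cannot be dialed in directly.

## Numerical choices

- **d′ clipping.** Hit/false-alarm rates are clipped to
  $[1/(2N),\, 1 - 1/(2N)]$ before the normal quantile, the standard
  correction that keeps d′ finite for perfect scores while converging to
  the true value as $N$ grows.
- **Balanced percent correct.** With equal target/foil counts, pooled pc
  equals $(p_\text{hit} + 1 - p_\text{FA})/2$ exactly on counts; the
  schedule guarantees the precondition.
- **Exclusions.** First 5 trials of each session are warm-up; subjects
  with <400 trials, >75% "old" responses, or <60% pc are excluded; any
  reported cell needs ≥20 trials. Performance is pooled with equal subject
  weighting (the subject, not the trial, is the replication unit).
- **Permutation tests.** Two-sided on the difference of group means, with
  the add-one estimator $p = (1 + k)/(n_\text{perm} + 1)$, so $p$ is never
  0 and the test is exact-level; Bonferroni adjustment uses the count of
  *eligible* properties in a batch, not the nominal inventory. With
  heavily tied discrete data the two-sided permutation p is conservative;
  group summaries fed to it (per-subject accuracies) are effectively
  continuous.
- **Consistency nulls.** Self: $(p^2, (1-p)^2, 2p(1-p))$ at the subject's
  own accuracy; pairwise: $(p_i p_j, (1-p_i)(1-p_j),
  p_i(1-p_j) + p_j(1-p_i))$. Deviations are tested by Monte-Carlo
  simulation of independent responders, two-sided on the inconsistent
  fraction.
- **Classifier.** Linear-kernel SVM (cost 1) via e1071, with balanced
  subsampling (all of the minority class plus an equal-size majority
  sample) so chance is 50%, stratified 10-fold cross-validation assigned
  by shot, and per-fold z-scoring estimated on training shots only.
  Accuracy is averaged over 25 balanced resamples; the SD is taken over
  repetition-by-fold accuracies. Stratified folds prevent the classic
  below-chance CV bias on shuffled labels: the label-shuffle null mean is
  50.05% ± 0.10% over 4,000 iterations on a 200-shot dataset.
- **Group regression.** OLS through a pivoted QR decomposition (aliased
  columns get coefficient 0); when there are fewer than 5 shots per
  feature a small ridge penalty ($\lambda = 10^{-3} n$) stabilizes the
  fit and is flagged. The reported $r^2$ is the squared correlation of
  held-out predictions with the actual per-shot group accuracies.
- **Majority/mode votes.** One vote per subject (first presentation);
  exact ties are excluded rather than broken arbitrarily, for labels,
  mode consistency, and the majority-of-others bound alike.
- **Retention curve.** Correlations over sessions use ordinal session
  rank, not elapsed days, since the nominal intervals are log-spaced by
  design.

## Design decisions

- Plain data.frame/S3 containers rather than a formal class hierarchy: the
  data are tabular behavioral trials and flow naturally through base R and
  CSV; the only structured objects are small report records with print
  methods.
- All file formats are text (CSV with 0/1 booleans and empty missing
  fields; JSON for nested reports), round-tripping byte-identically.
- Every stochastic entry point takes an explicit seed; the full pipeline
  (`run_pipeline`) is byte-deterministic given its seed.
- The command-line wrapper (`inst/cli/memovie.R`) is a thin shell over the
  exported functions; nothing is implemented only in the CLI.

## Worked example

```{r example}
library(memovie)
cfg <- generator_config(n_subjects = 12, n_shots_per_episode = 250,
                        seed = 42)
ds <- simulate_dataset(cfg)
ex <- apply_exclusions(ds$trials)
perf <- compute_performance(ex$trials)
perf$pooled

labels <- make_labels(ex$trials, level = "mode")
cls <- classify(ds$annotations, labels, seed = 1)
cls

run_pipeline(ds, "reports", seed = 1)
```
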