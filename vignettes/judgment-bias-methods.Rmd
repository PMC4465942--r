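---
title: "Measuring pessimism with a go/no-go judgment bias task: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pessimism with a go/no-go judgment bias task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(judgebias)
```

## The task and its logic

In a go/no-go judgment bias task an animal first learns an arbitrary
visual discrimination: lifting a pale grey cone (POS, 20% grey) is always
rewarded; lifting a dark grey cone (NEG, 60% grey) never is. Because the
subject is free to touch either cone, learning expresses itself not as a
binary go/no-go response but as a *latency difference*: well-trained
subjects touch POS quickly and hesitate on NEG. Once the discrimination
is in place, the subject is probed with cones of intermediate shade (NP
30%, M 40%, NN 50%) that are never rewarded and never seen in training.
A subject that treats ambiguity like the rewarded cue has a high
expectation of reward under uncertainty — an "optimistic" judgment bias;
one that treats it like the unrewarded cue is "pessimistic". This bias is
used as an objective behavioural marker of affective state.

The package implements the complete pipeline around that logic: session
scheduling with the protocol's pseudorandomization constraints, the
sequential progression criteria that decide when a subject moves from
training to testing, the latency statistics and the pessimism index, the
model fits used for inference, and a behavioural simulator that exercises
all of it end to end.

## The pessimism index

For a subject with mean responded test latencies $\bar L_{POS}$,
$\bar L_{NEG}$ and pooled intermediate mean $\bar L_I$:

$$\mathrm{index} = \frac{\bar L_I - \bar L_{POS}}
                        {\bar L_{NEG} - \bar L_{POS}}$$

Three numerical choices matter.

* **Raw seconds, not reciprocal.** The index is a ratio of latency
  *differences*, which makes it invariant under any common affine
  rescaling of the latencies (this is tested to 1e−12). Computing it on
  reciprocal latencies would destroy that invariance and change its
  anchoring. The reciprocal scale (1/latency, a speed) is used only
  inside the model fits, where it homogenises the right-skewed residuals.
* **Trial-weighted intermediate mean.** $\bar L_I$ pools all NP/M/NN
  trials rather than averaging the three per-valence means. With equal
  planned counts (3 per session each) the two coincide; after exclusions
  they differ, and pooling weights the evidence by what was actually
  observed. A `by_valence` variant is available in
  `subject_pessimism()` for sensitivity analysis.
* **No clipping.** Values below 0 (intermediates faster than POS) or
  above 1 (slower than NEG) are reported as computed; they are
  informative about poor discrimination rather than errors.

Test trials without a response within the 60-s cutoff are excluded from
*all* test-phase statistics, POS/NEG means included. Non-response in
testing is dominated by lapses of motivation or attention, not by the
cone's valence, so treating the cutoff as a real latency would inject
motivational noise into a cognitive measure. (In *training* the opposite
convention holds — see below.)

## Sequential progression criteria

Training and testing are gated by a small state machine
(`new_protocol_state()`, `advance_state()`), with every decision logged:

1. **Six-trial blocks.** 24-trial sessions of alternating same-valence
   blocks. After each session, a two-tailed two-sample t-test compares
   POS vs NEG latencies *cumulatively over all sessions of the phase*.
   A session counts only when p < α = 0.05 **and** the difference is in
   the predicted direction (POS faster). Progression requires three
   *successive* counting sessions, and no fewer than three sessions in
   total; any non-counting session resets the run.
2. **Three-trial blocks.** Same cumulative test; one counting session
   suffices.
3. **Choice sessions.** 24 simultaneous POS/NEG presentations; the
   criterion is an exact two-tailed binomial test of POS-first counts
   against ½. `min_significant_choices(24, 0.05)` enumerates the
   threshold: 18. A failed *first* choice session sends the subject back
   to three-trial blocks; within the test phase each of the five test
   sessions must be preceded by a passed choice session (a failed one is
   repeated).
4. **Test sessions.** Five 25-trial sessions; no criterion, data
   collection only.

During training, non-responses are *included* at a coded 61 s: a subject
that withholds responses to NEG is exhibiting exactly the discrimination
the criterion is looking for, so censored trials carry signal there.

Boundary conventions: p exactly equal to α does not count; the direction
check is always on raw-second means even if the test itself is configured
to run on reciprocal latencies.

Whether the cumulative training t-test should run on raw or reciprocal
latencies is genuinely ambiguous in the protocol this package
operationalises (the analysis convention transforms latencies, but the
training criterion is reported alongside means in seconds). The package
defaults to raw seconds and exposes
`protocol_config(training_scale = "reciprocal")`; the choice is flagged
here rather than silently made. The t-test variant is Welch by default —
fractional degrees of freedom in reported analyses of this design imply
unequal-variance tests — with the pooled form as an option.

## Schedules and "pseudorandom" constraints

The protocol's randomization is constrained, not free, and the
generators enforce the constraints exactly:

* six-trial blocks: each side used exactly 3 times per block;
* three-trial blocks: per-block balance is impossible (odd block size),
  so each valence gets exactly 6 left / 6 right per session;
* choice sessions: POS on each side exactly 12 times;
* test sessions: composition exactly 8 POS / 8 NEG / 3 NP / 3 M / 3 NN,
  every cone on the right (removing side-bias variance), first trial POS
  or NEG.

"Approximately evenly distributed with intermediates interspersed" is an
informal constraint; the package operationalises it as: no two
intermediate trials adjacent, and |#POS − #NEG| ≤ 2 within each half of
the session split at the break after trial 13. Orders are drawn by
seeded rejection sampling, so schedules are pure functions of
`(config, ordinal, seed)`. The concrete reading is a design choice of
this package; any order satisfying it is accepted by the conformance
checker.

## Models

* **Overall speed** (`fit_posneg_latency_model`): reciprocal latency of
  responded POS/NEG test trials on subject × test-session (both
  categorical, fixed). Subjects are deliberately *fixed* effects here —
  the questions are about these individuals, not a population. The
  session factor is the test-session number within subject (1–5), since
  subjects reach testing after different numbers of training sessions.
* **Intermediate cones** (`fit_intermediate_model`): reciprocal latency
  of responded NP/M/NN trials on percent grey (continuous), subject, and
  their interaction, with the per-session speed covariate
  (`session_speed`: mean reciprocal POS/NEG latency of that session)
  controlling for day-to-day motivation. ANOVA tables use sequential
  (type-I) sums of squares with the covariate entered *first*
  (`speed + chimp + valence + chimp:valence`). This ordering is the
  substantive point of including the covariate: entered later, the
  subject test would absorb session-level motivation differences and
  reject far too often when subjects truly differ only in motivation —
  null simulations with session-level speed variation confirm this
  (subject-effect false-positive rate ≈ 1% with the covariate first,
  ≈ 98% with it last).
* **Tukey HSD** (`tukey_hsd`): pairwise subject contrasts on adjusted
  means — each subject's model prediction at the grand mean of the
  covariate and valence — tested with the studentized-range
  distribution. How the covariate is handled in the HSD is not dictated
  by the protocol; adjusting to the covariate mean is this package's
  choice (it matches standard ANCOVA practice and reduces to the
  textbook HSD when there is no covariate, which is how the
  implementation is verified against `stats::TukeyHSD`). On the
  reciprocal scale sign conventions reverse: a positive difference means
  the first subject is *faster*.
* **Choice trend** (`fit_choice_trend`): square-root-transformed
  per-session POS-first proportions on session number, random intercept
  per subject, maximum likelihood (`nlme::lme`), slope tested by the
  change in deviance (χ², 1 df) when dropped. Here subjects *are* a
  random effect: the question ("does preference strengthen over
  sessions?") is general, not about named individuals.

All fixed-effect fits are verified against a direct normal-equations
solve; mixed-model LRTs are verified as twice the log-likelihood
difference.

## The behavioural simulator

`behavior_params()` defines a generative subject:

| parameter | meaning | default |
|---|---|---|
| `mu_log_lat` | log of the fully learned POS latency (log-s) | log 3.5 |
| `delta` | asymptotic NEG − POS latency difference (s) | 4 |
| `p_true` | true pessimism: standardized level of the mid cone | 0.5 |
| `gradient` | half-spread of NP/NN around `p_true` | 0.15 |
| `tau` | learning time constant (trials) | 80 |
| `sigma_sess` | SD of session-level motivation effect (log scale) | 0.15 |
| `sigma_trial` | SD of trial noise (log scale) | 0.3 |
| `p_nonresponse` | attention-lapse probability per trial | 0.02 |
| `beta_choice` | choice sensitivity | 5 |
| `n_pilot_trials` | pre-training trials credited to learning | 20 |

Mechanics: expected POS latency is `exp(mu_log_lat)`; the NEG expectation
sits `delta` above it, scaled by the learned discrimination fraction
`1 − exp(−trials_seen/tau)`; intermediates sit at standardized levels
`p_true ± gradient` and `p_true`, so the trial-weighted intermediate mean
recovers `p_true` exactly in expectation (the gradient cancels — chosen
deliberately so parameter recovery is a clean end-to-end check of the
whole pipeline, not of a lucky estimator). Latency draws are lognormal
(positive, right-skewed, as real latency data are), multiplied by a
per-session motivation effect; a trial becomes a non-response through an
attention lapse or by exceeding the 60-s cutoff — a mixture, because in
real data non-response is not confined to unrewarded valences. Choice
trials touch POS first with probability
`plogis(beta_choice × discrimination_frac)`, so preference starts at
chance and strengthens with learning.

The defaults are calibrated as a set of study-like conditions: subjects
finish block training in roughly 4–12 sessions, total training trials
(including the pilot credit) typically fall in the one-to-two-hundreds,
and the first choice session generally passes 18-of-24 — matching the
scale of the protocol the package was built around. Learning is a single
exponential because only training *totals* are knowable from typical
reports; no claim is made about the shape of real acquisition curves.

`simulate_subject()` runs the entire state machine — generating
schedules, drawing trials, evaluating criteria — and `generate_study()`
assembles a multi-subject dataset (default 3 subjects with `p_true` 0.2 /
0.5 / 0.8) plus a ground-truth sidecar.

### What the simulator does and does not emulate

It reproduces the *structure* the analyses assume: subject-specific
speed, POS < NEG latencies after learning, intermediates in between,
day-to-day motivation variation, lapses, censoring, strengthening choice
preference. It does not model boredom or fatigue within sessions,
learning that intermediates are unrewarded (real tasks can degrade over
repeated testing), social or mood dynamics over calendar time, or
reinforcement-learning structure. Passing recovery tests therefore shows
the pipeline measures what the generative model encodes — it cannot show
that real animals conform to that model.

## Verification strategy and problem sizes

The test suite runs each statistical primitive against an independent
oracle (full pmf enumeration for the binomial test over all n ≤ 50;
`stats::t.test`, normal equations, `stats::TukeyHSD` on balanced cases;
pooled recomputation for cumulative trajectories), property-style checks
under fixed seeds (schedule invariants over 200 seeds, affine invariance
to 1e−12, censoring consistency), and simulation-based checks sized to
keep the default suite fast while leaving clear margins: 100 low-noise
subjects for index recovery (observed: 100% within ±0.1 of truth), 100
replayed runs for criterion consistency (0 flags), 100 null and 100
strong-discrimination runs for the training criterion (≈ 1–3% vs 100%
completion within 10 sessions), and 100-replicate null simulations for
model false-positive rates. `scripts/acceptance.R` recomputes the same
headline quantities from a fresh seed at the same sizes.

One enumeration fact worth recording: the *fraction* of choices required
for significance is not pointwise monotone in session length (9/10 = 0.90
but 10/11 ≈ 0.91, both exact thresholds); only the absolute threshold is
monotone and the fraction trends down. The tests assert the true
properties.

## Known limitations

* The index is a *ranking* instrument: it orders subjects (or occasions)
  by pessimism but carries no clinical calibration on its own.
* Latency measures confound judgment with motivation; the speed
  covariate and the index's internal standardization control for
  session-level motivation, not for within-session drift.
* With a single random intercept and few subjects, the choice-trend
  model's χ² test is asymptotic; treat borderline p-values with care.
* Reproducing a specific study's subject-level tables requires that
  study's raw data; the package validates against simulation ground
  truth instead, plus the exactly determined quantities (thresholds,
  compositions, summary arithmetic).
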