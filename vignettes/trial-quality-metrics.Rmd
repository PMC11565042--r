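---
title: "Trial-level data-quality metrics: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-level data-quality metrics: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`trialqc` quantifies the quality of trial-level EEG/ERP single scores —
one number per trial, such as a time-window mean amplitude in microvolts
or a per-epoch band power. This vignette explains the estimators, the
tunable parameters and their defaults, the simulator used to test
everything, and the design decisions taken where the procedures are
genuinely underdetermined.

## The estimators

### Split-half reliability

Internal consistency asks how stably a measure ranks participants. One
iteration of the estimator, at subsample size $n$ (or with each
participant's full trial set for the *overall* scope):

1. draw $n$ trials per participant without replacement;
2. split them uniformly at random into two bins of sizes
   $\lfloor n/2\rfloor$ and $\lceil n/2\rceil$;
3. average each bin per participant;
4. Pearson-correlate the two half-mean vectors across participants,
   giving $r_\text{half}$;
5. apply the Spearman–Brown correction
   $r_\text{full} = 2r_\text{half}/(1+r_\text{half})$.

The iteration is repeated $B$ times (default $B = 1000$; the field
convention is 1000–5000) and the distribution of corrected coefficients is
summarized by its arithmetic mean and its percentile interval. Repeating
across a grid of $n$ (classically 5–100 in steps of 5) traces how
reliability grows with trial count, which is what trial-budget decisions
are read from.

Assumptions worth keeping in mind: the Pearson correlation underlying the
Spearman–Brown step presumes trials are exchangeable draws of a stable
construct. Tasks with learning, habituation, or condition changes over
time violate exchangeability, and the curve then mixes construct change
into "unreliability".

### Within-subject effect size

Per-participant trial means $\bar{x}_i$ are compared either to a baseline
constant $\mu_0$ (one-sample, $d = (\bar{x} - \mu_0)/s$, with
$t = d\sqrt{k}$) or between two conditions (paired,
$d = (\bar{x}_1 - \bar{x}_2)/s$ with the average-variance pooled SD
$s = \sqrt{(s_1^2+s_2^2)/2}$). Scores are assumed already
baseline-corrected, hence the default $\mu_0 = 0$. The same subsampling
grid applies; paired eligibility requires $n$ trials in *both* conditions.
The difference-score standardizer $d_z = \overline{\Delta}/s_\Delta$ is
available via `standardizer = "dz"` but is a different estimand and is
never silently substituted.

### Standardized measurement error

Per participant and condition with $N \ge 2$ trials, the analytic SME is
$\widehat{SD}/\sqrt{N}$ with the $k-1$ sample SD. The bootstrapped SME
resamples the $N$ trials with replacement $B$ times and reports the SD of
the resample means. Its large-$B$ limit is
$\text{aSME}\cdot\sqrt{(N-1)/N}$, because the bootstrap resamples the
empirical distribution (population-style SD): the factor is a property of
the estimator pair, documented and tested rather than "corrected", since
the two serve as mutual cross-validation. Group summaries average the
per-participant SMEs and attach a $t$-interval on the between-participant
variability. No quality thresholds are offered for SME — none are
established — and only mean-amplitude-type exchangeable scores are
accepted (no peak amplitudes, latencies, or waveforms).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `iterations` (B) | 1000 | count | convention is 1000–5000; 1000 gives a Monte-Carlo SE on the iteration mean far below dataset-level sampling error |
| `grid` | none (caller sets, e.g. `seq(5, 100, 5)`) | trials | trial-budget question at hand |
| `ci_level` | 0.95 | — | 2.5th/97.5th percentile convention |
| `baseline` (μ₀) | 0 | score units | inputs assumed baseline-corrected |
| `bootstrap_iterations` (SME) | 1000 | count | bootstrap SE of an SD is ≈ 1% at B = 5000; 1000 suffices for reporting |
| thresholds (plots) | .60/.80/.90 | reliability | conventional acceptable/good/excellent lines |

## The synthetic generator and what passing tests show

`synthetic_spec()` implements a two-variance-component model: subject $i$,
condition $c$, trial $t$ gives
$y_{ict} = \mu_c + b_i + e_{ict}$, $b_i \sim N(0,\sigma_b^2)$ shared
across conditions, $e_{ict} \sim N(0,\sigma_w^2)$. Closed forms follow:
single-trial reliability $\rho = \sigma_b^2/(\sigma_b^2+\sigma_w^2)$,
prophecy reliability $R(n) = n\rho/(1+(n-1)\rho)$, one-sample effect size
$d(n) = \mu_c/\sqrt{\sigma_b^2 + \sigma_w^2/n}$, expected aSME
$\sigma_w/\sqrt{n}$. These oracles are the backbone of the test suite: the
pipeline estimates must recover them within Monte-Carlo tolerances.

The generator emulates ragged trial counts, multiple conditions with mean
offsets, and shared subject effects (so null between-condition contrasts
have positively correlated scores, as real paired designs do). It does
*not* emulate: non-Gaussian amplitude distributions beyond the optional
scaled-$t$ noise, subject-by-condition interactions (an optional extension
knob exists but has no oracle), trial-order effects, artifacts, channel
structure, or anything about waveforms. Passing tests therefore show the
estimators are correct under exchangeable trial noise — not that any real
paradigm is reliable.

Gaussian components were chosen for closed-form tractability; condition
effects enter as mean shifts only, keeping the paired-d oracle simple.

## Numerical and procedural choices

- **Quantiles**: linear interpolation between order statistics
  (`stats::quantile` type 7; quantile $q$ at position $1+q(B-1)$).
- **Eligibility**: a participant with fewer than $n$ trials is excluded at
  that grid point, for *all* iterations, and `n_participants` is reported
  per point; grid points with fewer than 3 eligible participants are
  flagged unavailable instead of aborting the curve. Exclusion (rather
  than padding or sampling with replacement) keeps the estimand a
  shorter-experiment emulation. Eligibility is deliberately fixed across
  iterations so the participant set, and hence the estimand, is constant
  within a grid point.
- **Minimum participants = 3**: a Pearson correlation from 2 points is
  ±1 by construction.
- **Odd $n$**: bins of $\lfloor n/2\rfloor$ / $\lceil n/2\rceil$ and the
  Spearman–Brown step applied unchanged. The unequal halves make the
  corrected coefficient a slightly conservative estimate of $R(n)$ at odd
  $n$ (at $n=5$, $\rho=0.2$: ≈ 0.549 vs 0.556); this small bias is
  accepted and documented rather than patched with a length-specific
  prophecy, because the classic grid contains odd sizes.
- **Negative $r_\text{half}$** passes through the correction unclamped —
  truncation at 0 would bias the iteration mean upward. $r_\text{half}=-1$
  and zero-variance half vectors make an iteration undefined; such
  iterations are dropped from the summary and counted (`n_dropped`).
- **Iteration averaging**: arithmetic mean of corrected coefficients;
  a Fisher-$z$ mean is available (`average = "fisher"`) but non-default.
- **Overall effect-size CI**: the all-trials point estimate is
  deterministic, so its CI cannot come from trial resampling. The package
  bootstraps participants with replacement ($B$ draws) and reports the
  percentile interval — an interpretation, flagged as such, chosen because
  it answers the question users ask of that error bar (sampling
  variability across participants). The point estimate reported is the
  deterministic one, not the bootstrap mean.
- **Sample SD ($k-1$) everywhere**, including across bootstrap means, for
  internal consistency with the analytic SME definition.
- **RNG**: one master seed; per-(metric, contrast, $n$) sub-seeds derived
  by a 31-bit polynomial hash, so adding a grid point never perturbs other
  points and identical inputs reproduce identical outputs. Bit-equality
  across different implementations is not promised; statistical equality
  is.
- **Wide-CSV blanks** mean "trial absent", never zero: zero is a legal
  amplitude. Index positions of present trials are preserved.
- **Plot determinism**: each PNG gets a JSON sidecar recording points,
  intervals, and threshold lines; the sidecar is byte-stable, the PNG
  bytes are not promised to be.

## Problem sizes used in the tests

The suite exercises the estimators at 200 subjects / $B = 1000$ for the
oracle-recovery checks (prophecy curve within ±0.03 absolute, effect-size
curve within ±0.06), 20 000 iterations for the exhaustive-enumeration
check on a 3-participant, 2-trial design, $B = 5000$–50 000 for the
bootstrap-SME identities, and 500 subjects × 10 trials for the
split-half/Cronbach's-alpha cross-check (agreement within 0.05). These
sizes make Monte-Carlo error comfortably smaller than each stated band
while keeping the default test run quick.

## Known limitations

- Only trial-level single scores are accepted; nothing upstream
  (preprocessing, windowing, electrode clustering) is modelled, and no
  EEG recording formats are parsed.
- Reliability here is internal consistency of one session; it says
  nothing about test–retest stability, and no generalizability-theory
  decomposition is attempted.
- The alpha relationship (mean corrected split-half over all splits ≈
  Cronbach's alpha) is used only as a documented cross-check on balanced
  data, not as an estimator.
- The effect-size module reports no p-values and no multiple-comparison
  machinery; it is a measurement-planning tool, not an inference engine.
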