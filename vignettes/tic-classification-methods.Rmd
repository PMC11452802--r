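---
title: "Methods: tic summary scores, matched-pair cross-validation, and hybrid expert review"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tic summary scores, matched-pair cross-validation, and hybrid expert review}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ticscreen)
```

## The problem

Gilles de la Tourette syndrome (GTS) is diagnosed from the presence of motor
and vocal tics, and tic severity is commonly assessed from standardized
videos. Automated detectors can emit, for each 1-second interval of such a
video, a probability that a tic occurred. `ticscreen` implements everything
downstream of that per-second probability trace: per-video **tic summary
scores**, **video-level classification** of GTS versus healthy control (HC)
participants, and a **hybrid decision scheme** in which only low-confidence
automated predictions are referred to a human expert.

Healthy controls also produce spontaneous "extra movements" that a detector
will flag, so classification cannot rely on a zero-versus-nonzero signal;
both the *amount* and the *temporal structure* (clustering) of detected
events carry diagnostic information. That motivates the five scores and the
synthetic generator's design below.

## Tic summary scores

Let $p_1, \dots, p_L \in [0,1]$ be the per-second tic probabilities of a
video of $L$ seconds, and let $b_i = \mathbf{1}\{p_i \ge \tau\}$ be the
binarized tic indicators at detection threshold $\tau$ (default $0.5$). The
five per-video scores are:

1. **Proportion of tic intervals** (%): $100 \cdot \sum_i b_i / L$;
2. **Mean tic probability**: $\bar p = \sum_i p_i / L$ (raw probabilities,
   not binarized — it is a separate score, not a rescaling of score 1);
3. **Maximal tic segment** (s): length of the longest run of consecutive
   $b_i = 1$ (0 if no tic interval);
4. **Maximal tic-free segment** (s): longest run of $b_i = 0$;
5. **Tic clusters per minute**: number of maximal runs of $b_i = 1$ with
   length $\ge c$ seconds (default $c = 3$), divided by $L/60$.

Numerical conventions the definitions leave open, fixed here once:

* a probability exactly at the threshold counts as a tic (inclusive
  $\ge$), the conventional choice for a published threshold of 0.5;
* clusters are purely run-based: runs touching either end of the video
  count, and two runs separated by a single tic-free second are two
  clusters (no gap-merging);
* videos of any length are accepted and all rates are normalized by the
  actual length; the 150-second duration is a cohort convention, not a
  requirement of the scores.

The run-length kernel is `base::rle()` behind `run_lengths()`; the test
suite checks `compute_scores()` against an independent brute-force
per-second loop on a thousand random series.

## Classification model

Videos are classified by binomial logistic regression of group on one or
more summary scores,
$\operatorname{logit} P(\text{GTS} \mid x) = \beta_0 + \beta^\top x$,
fitted by iteratively reweighted least squares (Newton steps with
step-halving). Because univariate fits on small matched cohorts can separate
perfectly, the log-likelihood carries an optional tiny quadratic penalty
$\lambda \sum_j \beta_j^2$ on the slopes (default $\lambda = 10^{-6}$,
configurable to 0); a separation flag is raised when every observation is
fitted essentially exactly. Convergence is declared at penalized gradient
norm $10^{-8}$. With $\lambda = 0$ the fit agrees with `stats::glm` to
$10^{-6}$ (tested), and on a saturated two-cell design it recovers the
closed-form logit coefficients.

Predictors enter in their natural score units by default (coefficients stay
interpretable); an optional `standardize` flag z-scores them using
training-fold statistics only.

### Leave-pair-out cross-validation

Participants come in individually matched GTS/HC pairs, and each participant
contributes several videos. To preserve the matching and avoid optimistic
bias, every video's predicted probability comes from a model trained with
*all* videos of that video's participant **and** of the matched partner
removed — one fold per pair. `ticreg()` returns these cross-validated
probabilities together with the full-data fit; the test suite verifies each
fold against a from-scratch refit on the complement.

Performance is summarized at the video level by

* **balanced accuracy** — the arithmetic mean of sensitivity and
  specificity, with a video classified GTS at cross-validated probability
  $\ge 0.5$ (ties to GTS; the cohort is video-balanced by construction, but
  balanced accuracy keeps the metric honest anyway), and
* **AUROC** — computed from midranks, so it equals the Mann–Whitney
  probability that a random GTS video outranks a random HC video with ties
  counted one half, and is invariant under monotone transforms of the score.

Correlation between an automated score and manual tic counts is Pearson's
$r$ by default (Spearman by flag).

## Hybrid human/machine decision scheme

A cross-validated probability $p$ is **high-confidence** at threshold $t$
when $\max(p, 1-p) > t$ (strict, default $t = 0.9$; $p$ exactly at $t$ is
reviewed). High-confidence videos keep the automated classification;
low-confidence videos are referred to an expert, simulated as independent
label noise that reproduces the true group with probability
`expert_accuracy` (default 0.95). Difficulty-dependent expert error is
deliberately not modelled.

Two combined summaries are reported, because the within-subgroup quantities
are plain accuracies while an overall quality bound is usually wanted on the
balanced scale:

* the **analytic combined accuracy**
  $(n_{\text{high}} \cdot \text{acc}_{\text{high}} + n_{\text{low}} \cdot
  \text{acc}_{\text{expert}}) / n$ — a weighted mean of plain accuracies,
  exactly reconstructible from printed subgroup counts; and
* the **realized** plain and balanced accuracies of the actual hybrid
  decisions, including the simulated expert's mistakes.

`hybrid_sweep()` tabulates the review-burden/accuracy trade-off over a grid
of thresholds; raising the threshold can only grow the review set.

## Synthetic cohort generator

Real tic videos cannot be shared, so `generate_cohort()` produces a
structurally faithful stand-in on which every downstream stage is testable:

* **Hidden dynamics.** Each video is a two-state Markov chain
  (quiescent/tic) at 1-second resolution, started from its stationary
  distribution, with per-second transition probabilities `p_enter_tic` and
  `p_stay_tic`. This is the simplest process with the temporal clustering
  tics show: the stationary tic fraction is
  $p_{\text{enter}} / (p_{\text{enter}} + 1 - p_{\text{stay}})$ and tic
  runs are geometric with mean $1/(1-p_{\text{stay}})$ seconds — both
  closed forms are verified against simulation in the tests.
* **Emissions.** Each second's emitted probability is Beta-distributed with
  mean 0.8 (tic) or 0.2 (quiescent) and concentration 10 — bounded on
  $[0,1]$, unimodal, and noisy enough that traces cross the 0.5 threshold
  in both directions, as real detector output does.
* **Groups.** Defaults are `p_enter_tic = 0.05, p_stay_tic = 0.8` for GTS
  (stationary tic fraction 0.2, mean burst 5 s) and
  `p_enter_tic = 0.005, p_stay_tic = 0.3` for HC — controls produce sparse,
  short extra movements rather than an all-zero signal.
* **Heterogeneity.** Each participant's `p_enter_tic` is jittered on the
  log-odds scale with a $\mathcal{N}(0, 0.5^2)$ deviate, giving the
  few-tics/many-tics spread seen across patients while keeping probabilities
  in $(0,1)$.
* **Cohort layout.** 42 matched pairs by default; each pair draws its video
  count uniformly from 1–4 and both partners contribute that many
  150-second videos, so matching is a perfect bijection and video counts
  are pairwise balanced (enforced invariants).
* **Manual counts.** Each video carries a synthetic "manual tic count" —
  the number of hidden tic-run onsets, i.e. the generator's ground-truth
  event count — as a target for the correlation utility.
* **Seeding.** One master seed drives everything; participants use
  deterministic substream seeds, so cohorts are byte-identical across
  regenerations.

What the generator does **not** emulate: video content, detector error
structure (miscalibration, drift, per-region sensitivity), vocal tics, tic
suppression dynamics, demographic matching, or within-participant severity
trends. Passing tests on synthetic cohorts therefore demonstrate the
*statistical machinery* — not that any particular real-world accuracy would
be attained.

## Problem sizes and runtime choices

The test suite exercises full 42-pair cohorts (about 210 videos of 150 s)
where the design is at stake — null calibration over five seeds, the
well-separated regime pooled over three seeds — and smaller 6–12-pair
cohorts for structural contracts, keeping the whole suite under a minute.
The null-calibration check compares the across-seed mean against a 3-SE
band for a single cohort, which is conservative; the binomial/Mann–Whitney
standard errors ignore the within-participant correlation of videos, which
is why averaging over seeds matters there. The separated-regime check pools
cross-validated predictions over three seeds before stratifying by
confidence so the low-confidence subgroup is populated enough for a stable
accuracy ordering.

## Known limitations

* The expert model is exchangeable label noise; real expert error
  correlates with exactly the videos the classifier finds hard, so realized
  hybrid gains on real data may be smaller than the analytic formula
  suggests.
* Classification stays at the video level by design; aggregating multiple
  videos of a participant into a participant-level diagnosis is out of
  scope.
* The ridge default $10^{-6}$ stabilizes separated folds but leaves
  coefficients effectively unpenalized; it is not a tuning device, and no
  model selection across predictor subsets is performed beyond reporting
  per-predictor results.

## A compact example

```{r example}
cohort <- generate_cohort(sim_config(n_pairs = 12, seed = 42))
scores <- tic_scores(cohort)
fit <- ticreg(group ~ clusters_per_minute, scores)
fit
run_hybrid(fit, confidence_threshold = 0.9, expert_accuracy = 0.95, seed = 42)
```
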