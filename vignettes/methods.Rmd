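---
title: "Attention-weighted valuation under induced affect: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-weighted valuation under induced affect: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectgen)
```

## The scientific problem

When people meet a novel stimulus composed of familiar parts — a "compound"
of two reward-predictive cues — they must generalize: form a reward
expectation for the whole from what they know about the parts. How that
expectation comes out depends on how attention is distributed over the
parts. If attention is drawn to the higher-value cue, the compound looks
good; if it is drawn to the lower-value cue, the compound looks bad.
`affectgen` implements a complete simulation-and-analysis pipeline for a
three-phase probabilistic reward task built to measure exactly this, and for
the question of whether experimentally induced mood (positive, neutral,
negative) shifts that attentional weighting in an affect-congruent
direction.

## Task structure

The task has six rune cues, two at each generative reward probability
(25% = L, 50% = M, 75% = H); the assignment of cue identities to
probabilities is a seeded permutation. Three phases:

1. **Learning** — 144 feedback trials in 3 blocks of 48; each cue shown 24
   times, alone, against an empty planet that never pays out.
2. **Simple-cue test** — 30 no-feedback trials: every unordered cue pair
   twice.
3. **Compound generalization** — 96 no-feedback trials in 3 blocks of 32:
   16 *simple probe* trials (simple M vs an L/H compound), 24 *compound
   probe* trials (M/M vs L/H), and 56 non-probe trials with unequal mean
   values. Every single-cue stimulus in this phase carries an M cue, so
   probe preferences isolate within-compound attention.

Participants in the positive/negative groups additionally complete a
32-trial pre-induction baseline block (16 simple + 16 compound probes);
the neutral group does not.

Both probe types pit an L/H compound against an equal-mean alternative, so
any systematic preference reflects unequal attention to the L versus H cue,
not value differences.

### Design choices where the published totals leave freedom

The phase totals above are fixed, but their arrangement is not fully
specified, so the generator makes these choices (all configurable):

* **Non-probe composition.** The 56 non-probe trials default to 28
  simple-vs-compound (14 M vs L/M, 14 M vs M/H) and 28
  compound-vs-compound (14 L/H vs L/M, 14 L/H vs M/H) — the four pair
  types that the behavioral analyses score. The composition is a plain
  table (`generalization_composition()`) so an alternative design drops in.
* **Per-block tiling.** Each block receives the phase composition divided
  by three; remainders are dealt out by seeded draw under the constraint
  that every block holds exactly 32 trials. A composition that cannot tile
  into three equal blocks is rejected.
* **Cue sampling.** Which of the two same-class cues appears in a given
  stimulus is a seeded uniform draw.
* **Side assignment.** Within each trial class, the side of the
  higher-mean (or first-listed) option is counterbalanced across the phase
  to within one trial, with seeded order.

## The valuation model

Cue values are taken as the generative reward probabilities (0.25/0.5/0.75),
assuming the learning phase did its job; no trial-by-trial learning model is
fit. An empty planet is worth 0 and a simple stimulus is worth its cue's
value. A compound of cues with values $v_1, v_2$ is worth

$$V = \phi \sum_j A_j v_j, \qquad
A_j = \frac{e^{\alpha_V v_j}}{\sum_k e^{\alpha_V v_k}},$$

where $\alpha_V$ is the attention-to-value weight ($\alpha_V > 0$ draws
attention to the higher-value cue, $\alpha_V < 0$ to the lower-value cue,
$\alpha_V = 0$ gives equal weights) and $\phi$ is a compound multiplier
capturing a generic preference for compounds ($\phi > 1$) or simples
($\phi < 1$). $\phi$ never applies to simple stimuli. With $\phi = 1$ the
compound value is a weighted average and lies between its cue values —
the configural-generalization regime; $\phi = 2$ with equal attention
corresponds to elemental summation.

Choices are softmax in the two option values with inverse temperature
$\beta$:
$\Pr(\text{left}) = 1 / (1 + e^{-\beta (V_L - V_R)})$.

### Affect modulation

Affect condition is coded $+1/0/-1$. In post-induction generalization block
$b$ (zero-indexed), the effective parameters are

$$\alpha_V^{\text{eff}} = \alpha_V + \Delta\alpha_V \,\lambda^{b}\,
\text{Affect}, \qquad
\phi^{\text{eff}} = \phi + \Delta\phi \,\lambda^{b}\, \text{Affect},$$

with a common block-wise decay $\lambda$ ($\lambda = 1$: no decay;
$\lambda = 0$: the shift acts only in the first block, since $0^0 = 1$).
Pre-induction baseline trials and the simple-cue test always use the base
parameters. Effects of positive and negative affect are therefore symmetric
by construction; asymmetric variants are out of scope.

### The model family

Ten variants differ in which parameters are free
(`model_variant()`): `1` ($\beta$ only), `2` ($\beta, \phi$), `3`
($\beta, \alpha_V$), `4` ($\beta, \phi, \alpha_V$), and the second-stage
variants `4a/4b/4c` adding $\Delta\phi$, $\Delta\alpha_V$, or both, each
with or without a free $\lambda$ (`*_lam`). Fixed values are $\phi = 1$,
$\alpha_V = 0$, $\Delta = 0$, $\lambda = 1$.

### Likelihood scope

By default the likelihood covers the simple-cue test and all
compound-generalization trials (including the baseline block);
learning-phase choices are never modelled. A `phases` argument allows
generalization-only fits, since a first-stage analysis restricted to
"test-phase" choices admits both readings.

## Hierarchical Bayesian estimation

Participant-level parameters are sampled non-centered: raw values are
$\mu + \sigma z$ with $z \sim N(0,1)$, then mapped to their ranges with the
standard normal CDF — $\beta = \Phi(\text{raw}) \cdot 50$,
$\phi = \Phi(\text{raw}) \cdot 10$, $\lambda = \Phi(\text{raw}) \cdot 10$;
$\alpha_V$ and the $\Delta$s are identity-transformed. One group-level
Gaussian per parameter spans all participants regardless of affect group
(the affect condition acts only through the effective-parameter shift).
Priors are weakly informative on the raw scale: $\mu \sim N(0,1)$,
$\sigma \sim$ half-$N(0,1)$. These priors are a package choice — the
estimation procedure we follow specifies the transforms but not the priors —
and are deliberately mild relative to the CDF ranges.

The replication configuration is 4 chains of 2750 iterations with 1500
warmup, retaining 5000 draws; test-scale runs use 2 chains of 600/300.
Convergence is flagged (never silently dropped) when any split-half
$\widehat{R}$ reaches 1.1.

### Sampler

The default backend (`backend = "mwg"`) is an adaptive
Metropolis-within-Gibbs sampler written for this likelihood, interleaved
with an ancillarity-sufficiency (centered/non-centered) interweaving step
for the group-level parameters:

1. For each free parameter in turn, all participants' $z$ values receive
   independent random-walk proposals, evaluated against the data in one
   vectorized pass and accepted per participant; proposal scales adapt
   toward 44% acceptance during warmup.
2. Holding the participant raw values fixed, the group mean is redrawn from
   its conjugate Gaussian conditional and the group SD takes a log-scale
   random-walk step; the $z$ values are then recomputed. Because the raw
   values are untouched, this step costs no likelihood evaluations, yet it
   decorrelates the hierarchy the way interweaving strategies are designed
   to.

Divergence counts are reported as 0 — the concept does not apply to this
sampler family; convergence monitoring rests on split-$\widehat{R}$.
An identical model specification runs in JAGS (`backend = "jags"`), and the
test suite cross-checks the two backends' posterior summaries and WAIC on a
small cohort. The native sampler is the default because it evaluates the
fully vectorized likelihood and is roughly an order of magnitude faster on
cohort-sized problems, which makes the recovery studies below practical.

Numerical care: the softmax is evaluated through `plogis` on value
differences (max-subtraction equivalent for the two-option case), choice
probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ so the
log-likelihood stays finite even at $\beta = 50$ with values up to
$10 \times 0.75$, and the group SD is floored at $10^{-4}$ in the
interweaving step.

## Model comparison

`compute_waic()` implements WAIC on the deviance scale from the pointwise
log-likelihood matrix: $\text{lppd}_i = \log \frac1S \sum_s e^{\ell_{si}}$
(log-sum-exp stabilized), penalty $p_i = \mathrm{Var}_s(\ell_{si})$, and
$\text{WAIC} = -2(\text{lppd} - p_{\text{waic}})$; lower is better.
`compare_models()` reports each variant's difference to the minimum-WAIC
model with a standard error from the pointwise difference contributions,
$\mathrm{SE} = \sqrt{n \,\mathrm{Var}_i(d_i)}$ — the convention of the
`loo`-style pairwise comparison, applied on the deviance scale. The
minimum-WAIC model is selected unless twice the SE of its lead over a rival
overlaps zero, in which case the tie resolves toward fewer free parameters.
Per-observation (not per-participant) contributions enter the SE; grouping
by participant is a known alternative we did not adopt.

## Synthetic cohorts and recovery studies

`simulate_cohort()` draws participants from group-level Gaussians and plays
them through seeded schedules. Two hyperparameter regimes ship with the
package:

* `default_hyper()` — the *fitted-median regime*: raw means placed so the
  transformed medians sit at the group-level posterior medians of the full
  decay model fit to human data ($\alpha_V \approx -1$ with group SD 4.27,
  $\phi$ median 1.2 with transformed-scale SD about 0.19,
  $\Delta\alpha_V = 0.68$, $\Delta\phi = -0.03$, $\lambda = 0.45$) plus a
  plausible $\beta$ median of 8 (raw SD 0.4), which puts simulated
  simple-test accuracy in the low-0.9s, matching the observed 0.89. Group
  sizes default to 40/40/40.
* `prior_hyper()` — the raw-scale unit normal of the hierarchical prior;
  the default dispersion for recovery studies, whose original simulation
  settings are not published.

Learning-phase choices are simulated with the same softmax (cue value vs
the empty planet's 0), which yields occasional empty-planet choices for
low-$\beta$ participants and so exercises the exclusion filters; learning
outcomes are Bernoulli in the presented cue's probability. Choice noise is
softmax-only — no lapse parameter, as none appears in the model family.

`model_recovery()` simulates datasets from each candidate variant, fits all
candidates to each, and tallies the confusion matrix of generating versus
selected model; `parameter_recovery()` reports Spearman correlations
between true and posterior-median participant parameters. The published
validation design is 50 datasets x 100 participants; both functions default
to that scale and are run in this package's tests at reduced scale
(6 datasets x 40 participants, 2 chains x 600/300) with strongly separated
generating parameters, where correct selection is expected in a clear
majority of replicates.

What the generator deliberately does *not* emulate: reaction times, mood
self-reports, within-session drift in attention unrelated to affect, lapses,
and learning dynamics. Passing tests therefore validate the pipeline's
statistical machinery on data that satisfy the model's own assumptions; they
do not certify the model against the full richness of human data.

## Behavioral summaries and exclusions

`accuracy()` scores choices of the higher-value option (cue value in the
simple test; unweighted mean cue value in the generalization phase),
excluding equal-value (probe) trials. `probe_preference()` gives the
per-participant proportion of probe trials on which the L/H compound was
chosen. `split_half_reliability()` splits trials odd/even (or by seeded
random halves), correlates participant-level proportions across halves
(Spearman), and applies the Spearman-Brown step-up $2\rho/(1+\rho)$; the
odd/even default is a package choice where the original split is not
stated. `apply_exclusions()` flags participants whose simple-test accuracy
is not above chance (one-tailed binomial test, $\alpha = .05$, success =
higher-value choice on all 30 trials) or who chose the empty planet on more
than 25% of learning trials.

## Gaze analysis

Each cue on screen gets an area of interest: a full ellipse for a simple
cue, and for compounds a parent ellipse of twice the area
($\sqrt2$-scaled semi-axes) split along its minor axis into two
half-ellipses — so every cue's AoI area is identical across configurations.
Major axes are angled +45 degrees from vertical for the left stimulus and
-45 for the right; planets sit 13 cm diagonally above-left/above-right of
fixation, at 1 cm per degree of visual angle. The ellipse base size is not
published; the default semi-major axis is twice the 2.5 cm planet radius
and the semi-minor equals it, which encloses the planet while preserving
all stated area relations (any base size does). The default pixel scale is
28.2 px/cm on a 1024 x 768 display, origin top-left, y downward. Native
eye-tracker files are out of scope; input is a parsed fixation table.

`relative_looking_time()` sums in-AoI fixation durations in the pre-choice
window — fixations straddling the choice are clipped at the choice time
rather than dropped — and normalizes by total in-AoI time, returning that
total for downstream duration-weighting of trials. Boundary points count as
inside. `affect_congruent_rlt()` returns the looking proportion of the
affect-congruent cue (H under positive induction, L under negative) under
either denominator convention: relative to all cues on screen, or
renormalized within the L/H compound. `qc_exclusions()` flags participants
above Q3 + 1.5 IQR on any supplied quality metric (e.g. rater disagreement
in pixels, percentage of fixations outside any AoI).

`simulate_fixations()` closes the loop for testing: it emits fixation
streams whose expected dwell shares equal supplied attention weights, with
configurable off-AoI noise, landing points inside the correct (half-)
ellipses, and gamma-distributed (shape 4) segment durations. Feeding these
streams through the AoI pipeline recovers the generating weights as trial
count grows, which the test suite checks end to end.

## Problem sizes used in the shipped tests

The test suite runs everything at sizes chosen to exercise the full
pipeline: unit fits use 8-15 participants with 2 chains x 400-1400
iterations; the recovery checks use 6 datasets x 40 participants at
2 chains x 600/300 with strongly separated parameters; the replication
sampler-configuration check fits a 5-participant cohort at the full
4 x 2750/1500 budget; the directional replication simulates 300
participants per affect group (no fitting), where the expected ordering of
probe preferences (positive > neutral > negative, attenuating over blocks)
stands far clear of simulation noise.

## Known limitations

* Attention-to-certainty effects are not modelled (not identifiable in this
  task design), nor are asymmetric affect effects.
* The WAIC tie-break uses parameter count as a coarse complexity proxy;
  with nested variants this is the intended conservative behavior.
* The native sampler is a random-walk scheme: for very weakly identified
  parameters (e.g. $\lambda$ when the affect deltas are near zero) mixing
  is slower than gradient-based samplers would achieve, and short-chain
  fits can flag high split-$\widehat{R}$ on such parameters. The JAGS
  backend provides an independent check; neither backend is HMC.
* Cue values are assumed learned exactly; participants who learned poorly
  are handled by exclusion, not by modelling their learning.
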