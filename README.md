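# affectgen

Simulation and analysis tools for studying how induced affect biases
feature-based attention during **compound generalization** — the formation
of reward expectations for novel stimuli composed of familiar
reward-predictive cues.

The package is aimed at computational cognitive modellers and computational
psychiatry researchers. It covers the full pipeline around a three-phase
probabilistic reward task (cue learning, simple-cue test, compound
generalization with probe trials and an optional pre-induction baseline
block):

* seeded generation of the complete trial structure;
* an attention-weighted valuation model with softmax choice;
* simulation of participant cohorts from group-level hyperparameters;
* hierarchical Bayesian fitting of a ten-variant model family, WAIC model
  comparison, and model/parameter-recovery studies;
* model-free behavioral summaries, participant exclusion filters, and
  eye-tracking area-of-interest (AoI) relative-looking-time analysis.

## The model

Cue values are the generative reward probabilities
(L = 0.25, M = 0.5, H = 0.75). A compound of two cues is valued as

```
V = phi * sum_j A_j v_j,    A_j = exp(alpha_V * v_j) / sum_k exp(alpha_V * v_k)
```

where `alpha_V` biases attention toward higher- (`alpha_V > 0`) or
lower-value (`alpha_V < 0`) cues and `phi` scales compounds relative to
simple stimuli (which are worth their cue's value; empty planets are worth
0). Choices are softmax with inverse temperature `beta`. An affect
induction (coded +1/0/-1) shifts parameters with power-law block decay:

```
alpha_V(eff) = alpha_V + d_alpha_V * lambda^block * Affect
```

(and analogously for `phi`), with `block` zero-indexed over the
post-induction generalization blocks. Model variants free different
parameter subsets; see `?model_variant` and the methods vignette
(`vignettes/methods.Rmd`).

## Worked example

```r
library(affectgen)

# simulate a three-group cohort (40 per group, the study's design) from
# the fitted-median regime
coh <- simulate_cohort(c(positive = 40, neutral = 40, negative = 40),
                       variant = "4c_lam", seed = 1)
coh
#> <cohort> 120 participants ( negative:40, neutral:40, positive:40 );
#>   34960 trials; generating variant 4c_lam

# model-free summary: mean L/H probe preference by affect group
s <- participant_summary(coh)
pref <- (s$pref_simple_probe + s$pref_compound_probe) / 2
round(tapply(pref, s$condition, mean), 3)
#>    -1     0     1
#> 0.485 0.467 0.516

# fit the attention model; ~2 min on one core at this size
fit <- fit_hierarchical(coh, variant = "4", chains = 2, iter = 1500,
                        warmup = 500, seed = 2)
fit
#> <fit_result> variant 4 | 120 participants, 17680 observations
#>   2000 retained draws (2 chains x 1000), backend mwg
#>   max split-Rhat: 1.061 (converged)
lapply(posterior_summary(fit, "mu[alpha_v]", reference = 0), round, 3)
#> $median
#> [1] -0.76
#> $ci90
#> [1] -1.387 -0.161
#> $prob_exceeds
#> [1] 0.014

# compare against the no-attention baseline
cmp <- compare_models(list(
  fit_hierarchical(coh, variant = "1", chains = 2, iter = 1500, warmup = 500, seed = 2),
  fit))
cmp
#> Model comparison (WAIC, deviance scale; lower is better)
#>  model n_free    waic delta_waic se_delta selected
#>      1      1 21192.8    4129.01  107.934    FALSE
#>      4      3 17063.8       0.00       NA     TRUE
#> selected: 4
```

The negative group-mean `alpha_v` (posterior median -0.76, 90% CI excluding
zero) says simulated participants — like the humans whose posterior medians
seed the generator — weight the low-value cue in a compound more heavily,
and the WAIC comparison shows the attention parameter earns its keep. At 40
participants per group the affect-congruent ordering of probe preferences
(positive > neutral > negative) sits within sampling noise for any single
cohort, as the run above illustrates; the test suite checks the ordering on
a 400-per-group simulation where it stands clear of noise.

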