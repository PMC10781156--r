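# shared fixtures: built programmatically, cached per test run

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

test_cues <- function() cached("cues", make_cue_set(42))

cue_value_map <- function(cues = test_cues()) {
  stats::setNames(cues$reward_prob, cues$cue_id)
}

cue_of_class <- function(cls, which = 1L, cues = test_cues()) {
  cues$cue_id[cues$value_class == cls][which]
}

# a small mixed-condition cohort simulated from the fitted-median regime
small_cohort <- function() {
  cached("small_cohort",
         simulate_cohort(c(positive = 4, neutral = 4, negative = 4),
                         variant = "4c_lam", seed = 7))
}

# reduced sampler settings used throughout the unit tests
fast_fit <- list(chains = 2L, iter = 400L, warmup = 200L)

# random trial tables spanning all stimulus kinds, for likelihood oracles
random_trials <- function(n, cues = test_cues(), seed = 1) {
  withr::with_seed(seed, {
    mk_stim <- function() {
      kind <- sample(c("empty", "simple", "compound"), 1,
                     prob = c(0.15, 0.4, 0.45))
      switch(kind,
             empty = "",
             simple = sample(cues$cue_id, 1),
             compound = paste(sample(cues$cue_id, 2), collapse = "+"))
    }
    left <- character(n); right <- character(n)
    for (i in seq_len(n)) {
      repeat {
        l <- mk_stim(); r <- mk_stim()
        if (nzchar(l) || nzchar(r)) break
      }
      left[i] <- l; right[i] <- r
    }
    data.frame(
      phase = sample(c("simple_test", "generalization"), n, TRUE),
      block = sample(1:3, n, TRUE),
      trial_index = seq_len(n),
      left_cues = left, right_cues = right,
      trial_class = "mixed", feedback = FALSE,
      is_baseline = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.2, 0.8)),
      choice = sample(c("left", "right"), n, TRUE),
      stringsAsFactors = FALSE
    )
  })
}
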