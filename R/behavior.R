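#' Mean option values under equal attention (phi = 1, alpha_v = 0)
#'
#' The model-free "higher-value option" baseline: simple stimuli take their
#' cue value, compounds the unweighted mean of their two cue values, empty
#' planets 0.
#' @noRd
neutral_option_values <- function(trials, cues) {
  cue_values <- stats::setNames(cues$reward_prob, cues$cue_id)
  val <- function(ss) {
    vapply(ss, function(s) {
      cl <- stim_cues(s)
      if (!length(cl)) 0 else mean(cue_values[cl])
    }, 0, USE.NAMES = FALSE)
  }
  list(left = val(trials$left_cues), right = val(trials$right_cues))
}

#' Choice accuracy for a phase
#'
#' Proportion of trials on which the higher-value option was chosen, where
#' option value is the cue value (simple-cue test) or the unweighted mean of
#' cue values (generalization phase). Equal-value trials — the probe trials —
#' are excluded from the denominator.
#'
#' @param trials One participant's trials with a `choice` column.
#' @param cues Cue set.
#' @param phase Phase to score.
#' @return Proportion in [0, 1].
#' @export
accuracy <- function(trials, cues, phase = "simple_test") {
  tr <- trials[trials$phase == phase, , drop = FALSE]
  v <- neutral_option_values(tr, cues)
  eligible <- v$left != v$right
  if (!any(eligible)) stop("no trials with unequal option values in phase ", phase)
  tr <- tr[eligible, , drop = FALSE]
  higher_left <- v$left[eligible] > v$right[eligible]
  mean(ifelse(higher_left, tr$choice == "left", tr$choice == "right"))
}

#' Find which side holds the L/H compound (NA when absent)
#' @noRd
lh_side <- function(trials, cues) {
  cls <- stats::setNames(cues$value_class, cues$cue_id)
  is_lh <- function(ss) {
    vapply(ss, function(s) {
      cl <- stim_cues(s)
      length(cl) == 2L && setequal(cls[cl], c("L", "H"))
    }, TRUE, USE.NAMES = FALSE)
  }
  l <- is_lh(trials$left_cues)
  r <- is_lh(trials$right_cues)
  ifelse(l, "left", ifelse(r, "right", NA_character_))
}

#' Probe-trial preference for the L/H compound
#'
#' Proportion of probe trials of the requested type on which the L/H
#' compound was chosen over its equal-mean alternative (simple M for
#' `"simple_probe"`, M/M for `"compound_probe"`).
#'
#' @inheritParams accuracy
#' @param probe_type `"simple_probe"`, `"compound_probe"`, or both.
#' @param include_baseline Count pre-induction probe trials too?
#' @return Proportion choosing L/H.
#' @export
probe_preference <- function(trials, cues,
                             probe_type = c("compound_probe", "simple_probe"),
                             include_baseline = FALSE) {
  probe_type <- match.arg(probe_type, several.ok = TRUE)
  tr <- trials[trials$trial_class %in% probe_type, , drop = FALSE]
  if (!include_baseline && !is.null(tr$is_baseline)) {
    tr <- tr[!tr$is_baseline, , drop = FALSE]
  }
  if (!nrow(tr)) return(NA_real_)
  side <- lh_side(tr, cues)
  mean(tr$choice == side)
}

#' Spearman-Brown-corrected split-half reliability
#'
#' Splits each participant's binary trial outcomes into two halves
#' (odd/even trial order by default, or a seeded random split), computes
#' per-half proportions, correlates them across participants (Spearman),
#' and applies the Spearman-Brown correction `2 * rho / (1 + rho)`.
#'
#' @param outcomes Data.frame with `participant_id` and a 0/1 `outcome`
#'   column, trials in presentation order within participant.
#' @param split `"odd_even"` or `"random"`.
#' @param seed Seed for the random split.
#' @return List with `rho_half` (raw half correlation) and `rho_sb`
#'   (corrected); both NA with a warning when a half has zero variance
#'   across participants.
#' @export
split_half_reliability <- function(outcomes, split = c("odd_even", "random"),
                                   seed = NULL) {
  split <- match.arg(split)
  if (!all(outcomes$outcome %in% 0:1)) stop("outcomes must be 0/1")
  local_rng(seed)
  by_p <- split.data.frame(outcomes, outcomes$participant_id)
  if (any(vapply(by_p, nrow, 0L) < 2)) stop("need >= 2 trials per participant")
  halves <- vapply(by_p, function(df) {
    n <- nrow(df)
    idx <- if (split == "odd_even") seq_len(n) %% 2L == 1L else {
      h <- sample(n, n %/% 2L)
      seq_len(n) %in% h
    }
    c(mean(df$outcome[idx]), mean(df$outcome[!idx]))
  }, c(0, 0))
  if (stats::sd(halves[1, ]) == 0 || stats::sd(halves[2, ]) == 0) {
    warning("zero-variance half; reliability undefined")
    return(list(rho_half = NA_real_, rho_sb = NA_real_))
  }
  rho <- stats::cor(halves[1, ], halves[2, ], method = "spearman")
  list(rho_half = rho, rho_sb = 2 * rho / (1 + rho))
}

#' Participant exclusion filters
#'
#' Flags participants who (a) did not perform above chance in the simple-cue
#' test (one-tailed binomial test against 0.5 at alpha = .05 over the 30
#' test trials, success = choosing the higher-value cue) or (b) chose the
#' empty planet on more than 25% of learning trials. Decisions depend only
#' on each participant's own data.
#'
#' @param trials Cohort trial table (multiple participants) with choices.
#' @param cues Cue set.
#' @param alpha Binomial-test significance level.
#' @param empty_cutoff Maximum tolerated empty-planet choice proportion.
#' @return Data.frame per participant: accuracy counts, binomial p, empty
#'   proportion, individual flags, and `excluded`.
#' @export
apply_exclusions <- function(trials, cues, alpha = 0.05, empty_cutoff = 0.25) {
  by_p <- split.data.frame(trials, trials$participant_id)
  rows <- lapply(names(by_p), function(id) {
    tr <- by_p[[id]]
    test <- tr[tr$phase == "simple_test", , drop = FALSE]
    v <- neutral_option_values(test, cues)
    eligible <- v$left != v$right
    higher_left <- v$left[eligible] > v$right[eligible]
    correct <- ifelse(higher_left, test$choice[eligible] == "left",
                      test$choice[eligible] == "right")
    p_binom <- stats::binom.test(sum(correct), length(correct), 0.5,
                                 alternative = "greater")$p.value
    learn <- tr[tr$phase == "learning", , drop = FALSE]
    chose_empty <- ifelse(learn$choice == "left", learn$left_cues, learn$right_cues) == ""
    prop_empty <- mean(chose_empty)
    data.frame(participant_id = id,
               n_correct = sum(correct), n_test = length(correct),
               p_binom = p_binom, flag_learning = p_binom >= alpha,
               prop_empty = prop_empty, flag_empty = prop_empty > empty_cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$excluded <- out$flag_learning | out$flag_empty
  out
}

#' Per-participant behavioral summary for a cohort
#'
#' Simple-cue test accuracy, generalization accuracy on unequal-value
#' trials, probe preferences by type, and exclusion flags.
#'
#' @param cohort A [simulate_cohort()] result, or a trial table plus cues.
#' @param cues Cue set when `cohort` is a data.frame.
#' @return Data.frame, one row per participant.
#' @export
participant_summary <- function(cohort, cues = NULL) {
  if (inherits(cohort, "cohort")) {
    trials <- cohort$trials
    cues <- cohort$cues
  } else trials <- cohort
  excl <- apply_exclusions(trials, cues)
  by_p <- split.data.frame(trials, trials$participant_id)
  rows <- lapply(names(by_p), function(id) {
    tr <- by_p[[id]]
    data.frame(
      participant_id = id,
      condition = tr$condition[1],
      acc_simple_test = accuracy(tr, cues, "simple_test"),
      acc_generalization = accuracy(tr, cues, "generalization"),
      pref_simple_probe = probe_preference(tr, cues, "simple_probe"),
      pref_compound_probe = probe_preference(tr, cues, "compound_probe"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  merge(out, excl[, c("participant_id", "excluded")], by = "participant_id")
}
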