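#' Construct the six-cue set
#'
#' The task uses six rune cues: two with a low (25%), two with a medium (50%)
#' and two with a high (75%) generative reward probability. The assignment of
#' cue identifiers to reward probabilities is a seeded permutation, mirroring
#' the randomised allocation of cue images to probabilities across
#' participants.
#'
#' @param seed Integer seed controlling the id-to-probability permutation.
#' @return A data.frame with columns `cue_id`, `reward_prob` (one of 0.25,
#'   0.5, 0.75) and `value_class` (one of "L", "M", "H").
#' @examples
#' make_cue_set(1)
#' @export
make_cue_set <- function(seed = 0L) {
  probs <- rep(c(0.25, 0.5, 0.75), each = 2L)
  ids <- paste0("c", 1:6)
  rng <- local_rng(seed)
  assigned <- sample(probs)
  data.frame(
    cue_id = ids,
    reward_prob = assigned,
    value_class = value_class_of(assigned),
    stringsAsFactors = FALSE
  )
}

value_class_of <- function(p) {
  cls <- c("0.25" = "L", "0.5" = "M", "0.75" = "H")
  out <- cls[as.character(p)]
  if (anyNA(out)) stop("reward_prob must be one of 0.25, 0.5, 0.75")
  unname(out)
}

#' Scoped RNG: seed the caller's draws, restoring the global stream after
#' @noRd
local_rng <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = envir)
  invisible(NULL)
}

cues_of_class <- function(cues, cls) cues$cue_id[cues$value_class == cls]

#' Pick one of the two same-class cues, seeded upstream
#' @noRd
draw_cue <- function(cues, cls) {
  pool <- cues_of_class(cues, cls)
  pool[sample.int(length(pool), 1L)]
}

empty_stim <- function() ""

stim_str <- function(cue_ids) paste(cue_ids, collapse = "+")

#' Split a stimulus string into cue ids ("" = empty planet)
#' @noRd
stim_cues <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "+", fixed = TRUE)[[1]]
}

new_trials <- function(phase, block, left, right, trial_class, feedback,
                       is_baseline = FALSE) {
  n <- length(left)
  data.frame(
    phase = rep(phase, n),
    block = rep(block, length.out = n),
    trial_index = seq_len(n),
    left_cues = left,
    right_cues = right,
    trial_class = rep(trial_class, length.out = n),
    feedback = rep(feedback, length.out = n),
    is_baseline = rep(is_baseline, length.out = n),
    stringsAsFactors = FALSE
  )
}

#' Generate the cue-learning phase schedule
#'
#' 144 feedback trials in 3 blocks of 48; each cue appears 24 times (8 per
#' block), presented as a single cue on a random side with an empty planet
#' opposite. Sides are counterbalanced within block (4 left / 4 right per cue).
#'
#' @param cues Cue set from [make_cue_set()].
#' @param seed Integer seed.
#' @return Trial data.frame (see [generate_schedule()] for the column layout).
#' @export
generate_learning_phase <- function(cues, seed = 0L) {
  local_rng(seed)
  out <- vector("list", 3L)
  for (b in 1:3) {
    cue <- rep(cues$cue_id, each = 8L)
    side <- unlist(lapply(cues$cue_id, function(x) sample(rep(c("left", "right"), 4L))))
    ord <- sample.int(48L)
    cue <- cue[ord]; side <- side[ord]
    left <- ifelse(side == "left", cue, empty_stim())
    right <- ifelse(side == "right", cue, empty_stim())
    out[[b]] <- new_trials("learning", b, left, right, "learning", TRUE)
  }
  do.call(rbind, out)
}

#' Generate the simple-cue test schedule
#'
#' 30 no-feedback trials: each of the 15 unordered cue pairs twice, once in
#' each left/right orientation, in seeded-random order.
#'
#' @inheritParams generate_learning_phase
#' @export
generate_simple_test <- function(cues, seed = 0L) {
  local_rng(seed)
  pairs <- utils::combn(cues$cue_id, 2L)
  left <- c(pairs[1, ], pairs[2, ])
  right <- c(pairs[2, ], pairs[1, ])
  ord <- sample.int(30L)
  new_trials("simple_test", 1L, left[ord], right[ord], "simple_vs_simple", FALSE)
}

#' Default non-probe composition for the compound-generalization phase
#'
#' Phase totals: 16 simple probes (M vs L/H), 24 compound probes (M/M vs L/H)
#' and 56 non-probe trials split evenly over the four analysed pair types.
#' Rows give, per trial class, the two option templates (by value class,
#' "+"-joined for compounds) and the count across the phase.
#'
#' @return A data.frame with columns `trial_class`, `option_a`, `option_b`,
#'   `n`. `option_a` is the higher-mean option for non-probe classes.
#' @export
generalization_composition <- function() {
  data.frame(
    trial_class = c("simple_probe", "compound_probe",
                    rep("nonprobe_simple_vs_compound", 2L),
                    rep("nonprobe_compound_vs_compound", 2L)),
    option_a = c("L+H", "L+H", "M", "M+H", "L+H", "M+H"),
    option_b = c("M", "M+M", "L+M", "M", "L+M", "L+H"),
    n = c(16L, 24L, 14L, 14L, 14L, 14L),
    stringsAsFactors = FALSE
  )
}

instantiate_option <- function(cues, template) {
  cls <- strsplit(template, "+", fixed = TRUE)[[1]]
  if (length(cls) == 1L) return(draw_cue(cues, cls))
  if (cls[1] == cls[2]) {
    stim_str(sample(cues_of_class(cues, cls[1])))  # both same-class cues, random order
  } else {
    stim_str(c(draw_cue(cues, cls[1]), draw_cue(cues, cls[2])))
  }
}

#' Generate the compound-generalization phase schedule
#'
#' 96 no-feedback trials in 3 blocks of 32. Across the phase: 16 simple-probe
#' trials (simple M vs L/H compound), 24 compound-probe trials (M/M vs L/H),
#' and 56 non-probe trials with unequal mean values. Every simple stimulus in
#' this phase carries an M cue. Per-block composition is the phase composition
#' divided by 3 with remainders dealt out by seeded draw so each block has
#' exactly 32 trials; the left/right placement of each class's first-listed
#' option is counterbalanced to within one trial.
#'
#' @inheritParams generate_learning_phase
#' @param composition Class composition table, see
#'   [generalization_composition()].
#' @export
generate_generalization_blocks <- function(cues, seed = 0L,
                                           composition = generalization_composition()) {
  local_rng(seed)
  total <- sum(composition$n)
  if (total %% 3L != 0L) {
    stop("composition total (", total, ") cannot be tiled into 3 equal blocks")
  }
  per_block <- total %/% 3L
  base <- composition$n %/% 3L
  extra <- composition$n %% 3L
  # deal leftover trials of each row out so every block ends up with per_block
  units <- rep(seq_len(nrow(composition)), extra)
  n_extra_per_block <- per_block - sum(base)
  if (length(units) != 3L * n_extra_per_block) {
    stop("composition cannot be tiled into 3 equal blocks")
  }
  units <- sample(units)
  counts <- matrix(rep(base, 3L), ncol = 3L)  # rows: composition rows; cols: blocks
  if (length(units)) {
    blk_of_unit <- rep(1:3, each = n_extra_per_block)
    for (u in seq_along(units)) {
      counts[units[u], blk_of_unit[u]] <- counts[units[u], blk_of_unit[u]] + 1L
    }
  }
  # instantiate the whole phase, then deal trials out to blocks, so that the
  # side of each class's first-listed option is balanced across the phase
  rows <- rep(seq_len(nrow(composition)), composition$n)
  a <- vapply(rows, function(r) instantiate_option(cues, composition$option_a[r]), "")
  o <- vapply(rows, function(r) instantiate_option(cues, composition$option_b[r]), "")
  cls <- composition$trial_class[rows]
  a_left <- logical(total)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    a_left[idx] <- sample(rep(c(TRUE, FALSE), length.out = length(idx)))
  }
  blk <- integer(total)
  for (r in seq_len(nrow(composition))) {
    blk[rows == r] <- sample(rep(1:3, counts[r, ]))
  }
  left <- ifelse(a_left, a, o)
  right <- ifelse(a_left, o, a)
  out <- vector("list", 3L)
  for (b in 1:3) {
    idx <- sample(which(blk == b))
    out[[b]] <- new_trials("generalization", b, left[idx], right[idx],
                           cls[idx], FALSE)
  }
  do.call(rbind, out)
}

#' Generate the pre-induction baseline block
#'
#' 32 no-feedback trials (16 simple probes + 16 compound probes) completed by
#' the positive- and negative-affect groups before the first affect induction;
#' stored as block 0 with `is_baseline = TRUE`.
#'
#' @inheritParams generate_learning_phase
#' @export
generate_baseline_block <- function(cues, seed = 0L) {
  local_rng(seed)
  comp <- data.frame(
    trial_class = c("simple_probe", "compound_probe"),
    option_a = c("L+H", "L+H"),
    option_b = c("M", "M+M"),
    n = c(16L, 16L),
    stringsAsFactors = FALSE
  )
  rows <- rep(1:2, comp$n)
  a <- vapply(rows, function(r) instantiate_option(cues, comp$option_a[r]), "")
  o <- vapply(rows, function(r) instantiate_option(cues, comp$option_b[r]), "")
  cls <- comp$trial_class[rows]
  a_left <- logical(length(rows))
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    a_left[idx] <- sample(rep(c(TRUE, FALSE), length.out = length(idx)))
  }
  left <- ifelse(a_left, a, o)
  right <- ifelse(a_left, o, a)
  ord <- sample.int(length(rows))
  new_trials("generalization", 0L, left[ord], right[ord], cls[ord], FALSE,
             is_baseline = TRUE)
}

#' Build a full task design
#'
#' Combines the cue set with the three-phase trial schedule. The baseline
#' block is generated only when `include_baseline = TRUE` (the positive- and
#' negative-affect groups; the neutral group never receives one).
#'
#' @param seed Integer seed; sub-phase seeds are derived from it.
#' @param include_baseline Generate the 32-trial pre-induction block?
#' @param composition Non-probe composition table for the generalization
#'   phase.
#' @param cues Cue set to build the schedule from; defaults to a fresh
#'   seeded set (pass a shared set when several schedules must reference
#'   the same cue-to-probability assignment).
#' @return An object of class `task_design`: a list with `cues`, `schedule`
#'   (one data.frame over all phases) and `includes_baseline_block`.
#' @export
generate_schedule <- function(seed = 0L, include_baseline = FALSE,
                              composition = generalization_composition(),
                              cues = make_cue_set(seed)) {
  parts <- list(
    generate_learning_phase(cues, seed + 1L),
    generate_simple_test(cues, seed + 2L)
  )
  if (include_baseline) parts <- c(parts, list(generate_baseline_block(cues, seed + 3L)))
  parts <- c(parts, list(generate_generalization_blocks(cues, seed + 4L, composition)))
  sched <- do.call(rbind, parts)
  rownames(sched) <- NULL
  structure(
    list(cues = cues, schedule = sched, includes_baseline_block = include_baseline),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  tab <- table(x$schedule$phase)
  cat("<task_design> 6 cues;", nrow(x$schedule), "trials (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ");",
      if (x$includes_baseline_block) "with" else "no", "baseline block\n")
  invisible(x)
}

#' Write / read a trial schedule as TSV
#'
#' Columns: phase, block, trial_index, left_cues, right_cues, trial_class,
#' feedback, is_baseline (plus any extra columns present, e.g. choices).
#' Empty planets are stored as an empty field.
#'
#' @param schedule Trial data.frame.
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = NA)
  for (col in c("left_cues", "right_cues")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  df
}
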