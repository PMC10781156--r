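#' Transform a raw (unconstrained) parameter to its constrained range
#'
#' Participant-level parameters are sampled on an unconstrained ("raw")
#' scale and mapped to their ranges with the standard normal CDF:
#' `beta = pnorm(raw) * 50`, `phi = pnorm(raw) * 10`, `lam = pnorm(raw) * 10`;
#' `alpha_v`, `d_alpha_v` and `d_phi` are identity-transformed (real).
#'
#' @param raw Numeric vector on the raw scale.
#' @param param Parameter name (one of the six model parameters).
#' @return Transformed values.
#' @examples
#' transform_raw(0, "beta")  # 25
#' @export
transform_raw <- function(raw, param) {
  switch(param,
    beta = stats::pnorm(raw) * 50,
    phi = stats::pnorm(raw) * 10,
    lam = stats::pnorm(raw) * 10,
    alpha_v = ,
    d_alpha_v = ,
    d_phi = raw,
    stop("unknown parameter name: ", param)
  )
}

#' @rdname transform_raw
#' @param value Constrained-scale value to map back to the raw scale.
#' @export
raw_from_value <- function(value, param) {
  switch(param,
    beta = stats::qnorm(value / 50),
    phi = stats::qnorm(value / 10),
    lam = stats::qnorm(value / 10),
    alpha_v = ,
    d_alpha_v = ,
    d_phi = value,
    stop("unknown parameter name: ", param)
  )
}

#' Group-level hyperparameters
#'
#' Raw-scale group means and standard deviations for each model parameter.
#' `default_hyper()` encodes the "fitted-median regime" used for cohort
#' simulation: raw means are chosen so the transformed medians sit at the
#' group-level posterior medians of the full decay model fit to human data
#' (alpha_v ~ -1 with group SD 4.27, phi median ~1.2 with transformed-scale
#' SD ~0.19, d_alpha_v 0.68, d_phi -0.03, lam 0.45) and a plausible softmax
#' sharpness (beta ~ 8). `prior_hyper()` is the raw-scale unit normal of the
#' hierarchical prior, the default dispersion for recovery studies.
#'
#' @param ... Name = c(mean, sd) overrides on the raw scale, e.g.
#'   `alpha_v = c(5, 1)`.
#' @return A data.frame with columns `param`, `mean`, `sd` (raw scale).
#' @export
default_hyper <- function(...) {
  h <- data.frame(
    param = param_names(),
    mean = c(raw_from_value(8, "beta"),      # beta median 8
             raw_from_value(1.2, "phi"),     # phi median 1.2
             -1,                              # alpha_v
             -0.03,                           # d_phi
             0.68,                            # d_alpha_v
             raw_from_value(0.45, "lam")),   # lam median 0.45
    sd = c(0.4, 0.095, 4.27, 0.1, 0.5, 0.3),
    stringsAsFactors = FALSE
  )
  override_hyper(h, ...)
}

#' @rdname default_hyper
#' @export
prior_hyper <- function(...) {
  h <- data.frame(param = param_names(), mean = 0, sd = 1,
                  stringsAsFactors = FALSE)
  override_hyper(h, ...)
}

override_hyper <- function(h, ...) {
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% h$param) stop("unknown parameter name: ", nm)
    h$mean[h$param == nm] <- ov[[nm]][1]
    h$sd[h$param == nm] <- ov[[nm]][2]
  }
  if (any(h$sd < 0)) stop("hyper sd must be >= 0")
  h
}

#' Draw participant-level parameters (non-centered scheme)
#'
#' Each raw parameter is `mean + sd * z` with `z ~ N(0, 1)`, then
#' transformed to its constrained range via [transform_raw()].
#'
#' @param hyper Hyperparameter table, see [default_hyper()].
#' @param n Number of participants.
#' @param seed Integer seed (optional).
#' @return Data.frame of transformed parameters, one row per participant;
#'   raw values are kept in the attribute `"raw"`.
#' @export
draw_participant_params <- function(hyper, n = 1L, seed = NULL) {
  local_rng(seed)
  raw <- sapply(param_names(), function(nm) {
    row <- hyper[hyper$param == nm, ]
    if (!nrow(row)) stop("hyper table missing parameter: ", nm)
    row$mean + row$sd * stats::rnorm(n)
  })
  raw <- matrix(raw, nrow = n, dimnames = list(NULL, param_names()))
  out <- as.data.frame(sapply(param_names(), function(nm) transform_raw(raw[, nm], nm),
                              simplify = FALSE))
  attr(out, "raw") <- raw
  out
}

#' Simulate choices for one participant
#'
#' Draws each choice Bernoulli from the softmax probability of the
#' attention-weighted valuation under the participant's effective
#' parameters. Affect only acts on post-induction generalization blocks;
#' baseline and pre-induction phases are simulated with the base
#' parameters.
#'
#' @param params Free-parameter values for the participant.
#' @param trials Trial schedule data.frame.
#' @param cues Cue set.
#' @param affect Affect condition code (-1, 0, +1).
#' @param variant Model variant (object or id).
#' @param seed Integer seed (optional).
#' @return `trials` with a `choice` column added.
#' @export
simulate_choices <- function(params, trials, cues, affect,
                             variant = model_variant("4c_lam"), seed = NULL) {
  if (is.character(variant)) variant <- model_variant(variant)
  stopifnot(nrow(trials) > 0, affect %in% c(-1, 0, 1))
  local_rng(seed)
  p <- apply_variant(params, variant)
  d <- prep_choice_data(trials, cues)
  th <- lapply(stats::setNames(nm = param_names()), function(nm) rep(p[[nm]], d$n))
  dec <- th$lam^d$blk0 * (affect * d$aff_on)
  alE <- th$alpha_v + th$d_alpha_v * dec
  phE <- th$phi + th$d_phi * dec
  wL <- plogis(alE * (d$vL1 - d$vL2))
  wR <- plogis(alE * (d$vR1 - d$vR2))
  VL <- (1 + (phE - 1) * d$compL) * (wL * d$vL1 + (1 - wL) * d$vL2)
  VR <- (1 + (phE - 1) * d$compR) * (wR * d$vR1 + (1 - wR) * d$vR2)
  p_left <- plogis(th$beta * (VL - VR))
  trials$choice <- ifelse(stats::runif(d$n) < p_left, "left", "right")
  trials
}

#' Simulate reward outcomes for the learning phase
#'
#' Each learning trial's presented cue yields reward with its generative
#' probability; empty planets are never rewarded. The `reward` column gives
#' the outcome of the cue-bearing planet (the outcome a chooser of that
#' planet would observe).
#'
#' @param trials Trial data.frame (learning-phase rows are used).
#' @param cues Cue set.
#' @param seed Integer seed (optional).
#' @return The learning-phase rows of `trials` with a `reward` column.
#' @export
simulate_learning_outcomes <- function(trials, cues, seed = NULL) {
  local_rng(seed)
  tr <- trials[trials$phase == "learning", , drop = FALSE]
  if (!nrow(tr)) stop("no learning-phase trials")
  cue_values <- stats::setNames(cues$reward_prob, cues$cue_id)
  cue <- ifelse(nzchar(tr$left_cues), tr$left_cues, tr$right_cues)
  pr <- cue_values[cue]
  tr$reward <- as.integer(stats::runif(nrow(tr)) < pr)
  if (!is.null(tr$choice)) {
    chose_empty <- ifelse(tr$choice == "left", tr$left_cues, tr$right_cues) == ""
    tr$reward_received <- ifelse(chose_empty, 0L, tr$reward)
  }
  tr
}

#' Simulate a cohort of participants
#'
#' Generates, per participant: an affect condition, true model parameters
#' drawn from the group-level hyperparameters, a full seeded task schedule
#' (with the 32-trial baseline block for the positive/negative groups only),
#' learning-phase outcomes, and softmax choices for every phase (learning
#' trials are choices between the presented cue and the empty planet).
#'
#' @param n_per_group Named integer vector of group sizes
#'   (positive/neutral/negative).
#' @param variant Generating model variant.
#' @param hyper Hyperparameter table; see [default_hyper()].
#' @param seed Integer seed for the whole cohort.
#' @param conditions Conditions to simulate; defaults to all three.
#' @return An object of class `cohort`: list with `cues`, `participants`
#'   (id, condition, true transformed and raw parameters) and `trials`
#'   (stacked per-participant schedules with `participant_id`, `condition`,
#'   `choice`, and `reward` on learning trials).
#' @export
simulate_cohort <- function(n_per_group = c(positive = 40, neutral = 40, negative = 40),
                            variant = model_variant("4c_lam"),
                            hyper = default_hyper(), seed = 0L,
                            conditions = c("positive", "neutral", "negative")) {
  if (is.character(variant)) variant <- model_variant(variant)
  n_per_group <- n_per_group[conditions[conditions %in% names(n_per_group)]]
  n <- sum(n_per_group)
  if (n < 1) stop("cohort must contain at least one participant")
  cues <- make_cue_set(seed)
  params <- draw_participant_params(hyper, n, seed = derive_seed(seed, 1L))
  code_of <- c(positive = 1, neutral = 0, negative = -1)
  condition <- rep(names(n_per_group), n_per_group)
  participants <- data.frame(
    participant_id = sprintf("p%03d", seq_len(n)),
    condition = condition,
    affect = unname(code_of[condition]),
    stringsAsFactors = FALSE
  )
  participants <- cbind(participants, params)
  attr(participants, "raw") <- attr(params, "raw")

  trials <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, 100L + i)
    des <- generate_schedule(si, include_baseline = participants$affect[i] != 0,
                             cues = cues)
    tr <- simulate_choices(params[i, ], des$schedule, cues,
                           affect = participants$affect[i], variant = variant,
                           seed = derive_seed(si, 1L))
    lo <- simulate_learning_outcomes(tr, cues, seed = derive_seed(si, 2L))
    tr$reward <- NA_integer_
    tr$reward[tr$phase == "learning"] <- lo$reward
    tr <- cbind(participant_id = participants$participant_id[i],
                condition = unname(code_of[participants$condition[i]]), tr)
    trials[[i]] <- tr
  }
  structure(
    list(cues = cues, participants = participants,
         trials = do.call(rbind, trials), variant = variant$id, seed = seed),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$participants), "participants (",
      paste(names(table(x$participants$condition)),
            table(x$participants$condition), sep = ":", collapse = ", "),
      ");", nrow(x$trials), "trials; generating variant", x$variant, "\n")
  invisible(x)
}

#' Derive a reproducible sub-seed (kept within 32-bit integer range)
#' @noRd
derive_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) * 7919 + i * 104729 + j * 611953) %% 2147483647)
}

#' Write a simulated cohort to a directory
#'
#' Writes `choices.tsv` (trial table), `cues.json`, and `truth.json`
#' (participant conditions and true parameters) as plain text.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_schedule(cohort$trials, file.path(dir, "choices.tsv"))
  jsonlite::write_json(cohort$cues, file.path(dir, "cues.json"), digits = NA)
  jsonlite::write_json(cohort$participants, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
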