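#' Model variant registry
#'
#' The model family shares six participant-level parameters: softmax inverse
#' temperature `beta` (0, 50); compound scaling multiplier `phi` (0, 10);
#' attention-to-value weight `alpha_v` (real); affect-related changes
#' `d_phi` and `d_alpha_v` (real); and block-wise decay `lam` (0, 10).
#' Variants differ in which parameters are free:
#' \itemize{
#'   \item `"1"`: beta only (phi = 1, alpha_v = 0).
#'   \item `"2"`: beta, phi (alpha_v = 0).
#'   \item `"3"`: beta, alpha_v (phi = 1).
#'   \item `"4"`: beta, phi, alpha_v.
#'   \item `"4a"` / `"4a_lam"`: adds d_phi (and lam).
#'   \item `"4b"` / `"4b_lam"`: adds d_alpha_v (and lam).
#'   \item `"4c"` / `"4c_lam"`: adds both deltas (and lam).
#' }
#' When `lam` is not free it is fixed at 1 (no decay of affect effects).
#'
#' @param id Variant id string.
#' @return A list with `id`, `free` (free parameter names) and `fixed`
#'   (named numeric vector of fixed values).
#' @export
model_variant <- function(id) {
  id <- as.character(id)
  base <- c("beta", "phi", "alpha_v")
  free <- switch(id,
    "1" = "beta",
    "2" = c("beta", "phi"),
    "3" = c("beta", "alpha_v"),
    "4" = base,
    "4a" = c(base, "d_phi"),
    "4a_lam" = c(base, "d_phi", "lam"),
    "4b" = c(base, "d_alpha_v"),
    "4b_lam" = c(base, "d_alpha_v", "lam"),
    "4c" = c(base, "d_phi", "d_alpha_v"),
    "4c_lam" = c(base, "d_phi", "d_alpha_v", "lam"),
    stop("unknown model variant: ", id)
  )
  defaults <- c(beta = NA_real_, phi = 1, alpha_v = 0,
                d_phi = 0, d_alpha_v = 0, lam = 1)
  fixed <- defaults[setdiff(names(defaults), free)]
  structure(list(id = id, free = free, fixed = fixed), class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat("<model_variant", x$id, "> free:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

param_names <- function() c("beta", "phi", "alpha_v", "d_phi", "d_alpha_v", "lam")

#' Impose a variant's fixed parameter values on a parameter set
#'
#' @param params Named list or one-row data.frame with any of the six model
#'   parameters; missing free parameters are an error.
#' @param variant A [model_variant()].
#' @return Named numeric vector over all six parameters.
#' @export
apply_variant <- function(params, variant) {
  params <- as.list(params)
  out <- stats::setNames(numeric(6), param_names())
  for (nm in param_names()) {
    if (nm %in% variant$free) {
      if (is.null(params[[nm]])) stop("free parameter '", nm, "' missing")
      out[nm] <- params[[nm]]
    } else {
      out[nm] <- variant$fixed[[nm]]
    }
  }
  out
}

#' Value-based attention weights within a compound
#'
#' Softmax of cue values scaled by the attention-to-value weight:
#' \eqn{A_j = \exp(\alpha_V v_j) / \sum_k \exp(\alpha_V v_k)}. Positive
#' `alpha_v` draws attention toward higher-value cues, negative toward
#' lower-value cues; zero gives equal weights.
#'
#' @param alpha_v Attention-to-value weight (real).
#' @param values Numeric vector of cue values.
#' @return Weights, positive and summing to 1.
#' @examples
#' attention_weights(1, c(0.25, 0.75))
#' @export
attention_weights <- function(alpha_v, values) {
  if (!length(values)) stop("values must be non-empty")
  x <- alpha_v * values
  x <- x - max(x)  # stabilized softmax
  e <- exp(x)
  e / sum(e)
}

#' Value of a stimulus under the attention-weighted model
#'
#' Empty planets have value 0; a simple stimulus takes the value of its cue
#' (the compound multiplier does not apply); a compound takes
#' \eqn{\phi \sum_j A_j v_j} with attention weights from
#' [attention_weights()].
#'
#' @param stimulus Character vector of cue ids (length 0, 1 or 2), or a
#'   single "+"-joined string such as `"c1+c4"` (`""` = empty planet).
#' @param cue_values Named numeric vector mapping cue id to value.
#' @param phi_eff Effective compound multiplier.
#' @param alpha_v_eff Effective attention-to-value weight.
#' @export
stimulus_value <- function(stimulus, cue_values, phi_eff = 1, alpha_v_eff = 0) {
  if (length(stimulus) == 1L && (is.na(stimulus) || grepl("+", stimulus, fixed = TRUE) ||
                                 !nzchar(stimulus))) {
    stimulus <- stim_cues(stimulus)
  }
  if (!length(stimulus)) return(0)
  bad <- setdiff(stimulus, names(cue_values))
  if (length(bad)) stop("unknown cue id(s): ", paste(bad, collapse = ", "))
  v <- cue_values[stimulus]
  if (length(v) == 1L) return(unname(v))
  a <- attention_weights(alpha_v_eff, v)
  phi_eff * sum(a * v)
}

#' Effective parameters under an affect induction
#'
#' The affect induction shifts `alpha_v` and `phi` by the affect-related
#' change scaled by a power-law decay over blocks:
#' \eqn{\alpha_V^{eff} = \alpha_V + \Delta\alpha_V \lambda^{block} A} (and
#' likewise for `phi`), where `A` is the signed affect code (+1 positive,
#' 0 neutral, -1 negative) and `block` is zero-indexed so the first
#' post-induction block gets the full shift (\eqn{\lambda^0 = 1}, including
#' at \eqn{\lambda = 0}). Pre-induction (baseline) trials and the neutral
#' condition use the base parameters.
#'
#' @param params Named parameter vector/list (see [apply_variant()]).
#' @param affect Affect code in -1, 0, +1.
#' @param block Zero-indexed generalization block (vectorized, >= 0).
#' @param is_baseline Logical; pre-induction trials (vectorized).
#' @return List with `alpha_v_eff` and `phi_eff` (same length as `block`).
#' @export
effective_params <- function(params, affect, block, is_baseline = FALSE) {
  stopifnot(affect %in% c(-1, 0, 1))
  if (any(block < 0)) stop("block must be zero-indexed and non-negative")
  params <- as.list(params)
  mult <- ifelse(is_baseline, 0, affect) * params$lam^block
  list(
    alpha_v_eff = params$alpha_v + params$d_alpha_v * mult,
    phi_eff = params$phi + params$d_phi * mult
  )
}

#' Softmax choice probabilities for a two-option trial
#'
#' @param v_left,v_right Option values (vectorized).
#' @param beta Inverse temperature (>= 0); 0 gives random choice.
#' @return List with `p_left`, `p_right`.
#' @export
choice_prob <- function(v_left, v_right, beta) {
  if (any(beta < 0)) stop("beta must be non-negative")
  p <- plogis(beta * (v_left - v_right))
  list(p_left = p, p_right = 1 - p)
}

# guard against p = 0/1 exactly; beta <= 50 with |dV| up to ~7.5 can saturate
clamp_p <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Precompute per-trial numeric arrays for likelihood evaluation
#'
#' Encodes each option as (v1, v2, is_compound): simple stimuli carry their
#' cue value twice with is_compound = 0 (so the attention-weighted average
#' is the cue value and the compound multiplier does not apply); empty
#' planets carry zeros. Also derives the zero-indexed decay block and the
#' per-trial affect multiplier switch (nonzero only on post-induction
#' generalization trials).
#'
#' @noRd
prep_choice_data <- function(trials, cues) {
  cue_values <- stats::setNames(cues$reward_prob, cues$cue_id)
  enc <- function(ss) {
    cl <- lapply(ss, stim_cues)
    n <- lengths(cl)
    bad <- setdiff(unlist(cl), names(cue_values))
    if (length(bad)) stop("unknown cue id(s): ", paste(bad, collapse = ", "))
    v1 <- numeric(length(ss)); v2 <- numeric(length(ss))
    v1[n >= 1] <- cue_values[vapply(cl[n >= 1], `[`, "", 1L)]
    v2[n == 1] <- v1[n == 1]
    v2[n == 2] <- cue_values[vapply(cl[n == 2], `[`, "", 2L)]
    list(v1 = v1, v2 = v2, comp = as.numeric(n == 2L))
  }
  L <- enc(trials$left_cues); R <- enc(trials$right_cues)
  if (any(trials$left_cues == "" & trials$right_cues == "")) {
    stop("trial with two empty planets has no defined choice model")
  }
  is_base <- if (!is.null(trials$is_baseline)) trials$is_baseline else FALSE
  aff_on <- as.numeric(trials$phase == "generalization" & !is_base)
  blk0 <- pmax(trials$block - 1L, 0L)
  list(vL1 = L$v1, vL2 = L$v2, compL = L$comp,
       vR1 = R$v1, vR2 = R$v2, compR = R$comp,
       blk0 = blk0, aff_on = aff_on, n = nrow(trials))
}

#' Per-trial choice log-likelihood from prepared arrays (vectorized core)
#'
#' `th` holds per-trial parameter values (already indexed by participant).
#' `aff` is the signed per-trial affect multiplier (condition code, zeroed
#' on baseline / pre-induction trials).
#' @noRd
trial_loglik_core <- function(th, d, aff, y_left) {
  dec <- th$lam^d$blk0 * aff
  alE <- th$alpha_v + th$d_alpha_v * dec
  phE <- th$phi + th$d_phi * dec
  wL <- plogis(alE * (d$vL1 - d$vL2))
  wR <- plogis(alE * (d$vR1 - d$vR2))
  VL <- (1 + (phE - 1) * d$compL) * (wL * d$vL1 + (1 - wL) * d$vL2)
  VR <- (1 + (phE - 1) * d$compR) * (wR * d$vR1 + (1 - wR) * d$vR2)
  p <- clamp_p(plogis(th$beta * (VL - VR)))
  ifelse(y_left, log(p), log1p(-p))
}

#' Choice log-likelihood of a dataset under a model variant
#'
#' Evaluates the attention-weighted valuation model with softmax choice for
#' one participant's recorded choices. Which phases enter the likelihood is
#' controlled by `phases`; the default models the simple-cue test and all
#' compound-generalization trials (learning-phase choices are never
#' modelled). Affect enters only on post-induction generalization trials.
#'
#' @param params Free-parameter values (named list/vector); fixed values are
#'   imposed by `variant`.
#' @param trials Trial data.frame including a `choice` column ("left" or
#'   "right").
#' @param cues Cue set data.frame.
#' @param affect Affect condition code (-1, 0, +1).
#' @param variant A [model_variant()] or id string.
#' @param phases Phases entering the likelihood.
#' @return List with `total` (sum of per-trial log-likelihoods), `pointwise`
#'   (per-trial vector, for WAIC) and `used` (row indices of `trials` used).
#' @export
dataset_loglik <- function(params, trials, cues, affect,
                           variant = model_variant("4"),
                           phases = c("simple_test", "generalization")) {
  if (is.character(variant)) variant <- model_variant(variant)
  stopifnot(affect %in% c(-1, 0, 1))
  use <- which(trials$phase %in% phases)
  tr <- trials[use, , drop = FALSE]
  if (!nrow(tr)) stop("no trials in the requested phases")
  if (!all(tr$choice %in% c("left", "right"))) {
    stop("every modelled trial needs a choice of 'left' or 'right'")
  }
  p <- apply_variant(params, variant)
  d <- prep_choice_data(tr, cues)
  th <- lapply(stats::setNames(nm = param_names()), function(nm) rep(p[[nm]], d$n))
  ll <- trial_loglik_core(th, d, aff = affect * d$aff_on, y_left = tr$choice == "left")
  list(total = sum(ll), pointwise = ll, used = use)
}
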