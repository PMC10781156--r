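#' Model-recovery study
#'
#' For each generating variant: simulate `n_datasets` cohorts, fit every
#' candidate variant to each, select by [compare_models()], and tally the
#' confusion matrix of generating x selected variant. Variants without
#' affect parameters are simulated and assessed on neutral-condition data
#' only (the first-stage design); variants with affect parameters simulate
#' all three conditions. Unconverged fits are propagated into the report,
#' never dropped.
#'
#' @param variants Character vector of candidate variant ids (>= 2).
#' @param n_datasets Simulated datasets per generating variant.
#' @param n_participants Participants per dataset (evenly split over the
#'   simulated conditions).
#' @param hyper Hyperparameter table for the generating parameters
#'   (default: the unit-normal raw-scale prior dispersion).
#' @param chains,iter,warmup Sampler budget per fit.
#' @param seed Integer seed for the whole study.
#' @param backend Sampler backend.
#' @return A `recovery_report` with `confusion` (counts matrix),
#'   `selections`, `unconverged` (count of fits flagged), and the scale
#'   settings.
#' @export
model_recovery <- function(variants, n_datasets = 50L, n_participants = 100L,
                           hyper = prior_hyper(), chains = 2L, iter = 600L,
                           warmup = 300L, seed = 1L, backend = "mwg") {
  if (length(variants) < 2) stop("need at least 2 variants")
  confusion <- matrix(0L, length(variants), length(variants),
                      dimnames = list(generating = variants, selected = variants))
  unconv <- 0L
  sel_log <- list()
  for (g in seq_along(variants)) {
    gv <- model_variant(variants[g])
    affective <- any(c("d_phi", "d_alpha_v", "lam") %in% gv$free)
    conds <- if (affective) c("positive", "neutral", "negative") else "neutral"
    npg <- stats::setNames(rep(ceiling(n_participants / length(conds)), length(conds)),
                           conds)
    for (ds in seq_len(n_datasets)) {
      s <- derive_seed(seed, g, ds)
      coh <- simulate_cohort(npg, variant = gv, hyper = hyper, seed = s,
                             conditions = conds)
      fits <- lapply(seq_along(variants), function(v) {
        fit_hierarchical(coh, variant = variants[v], chains = chains,
                         iter = iter, warmup = warmup,
                         seed = derive_seed(s, v), backend = backend)
      })
      unconv <- unconv + sum(!vapply(fits, `[[`, TRUE, "converged"))
      cmp <- compare_models(fits)
      sel <- attr(cmp, "selected")
      confusion[variants[g], sel] <- confusion[variants[g], sel] + 1L
      sel_log[[length(sel_log) + 1L]] <- data.frame(
        generating = variants[g], dataset = ds, selected = sel,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    confusion = confusion,
    selections = do.call(rbind, sel_log),
    unconverged = unconv,
    settings = list(variants = variants, n_datasets = n_datasets,
                    n_participants = n_participants, chains = chains,
                    iter = iter, warmup = warmup, seed = seed)
  ), class = "recovery_report")
}

#' Parameter-recovery study
#'
#' Simulates `n_participants` with dispersed true parameters, fits the same
#' variant, and reports the Spearman correlation between true and estimated
#' (posterior-median) values for each free parameter.
#'
#' @inheritParams model_recovery
#' @param variant Variant to simulate from and fit.
#' @return A `recovery_report` with `spearman` (named rho per free
#'   parameter), `estimates` (true and estimated per participant), and the
#'   fit itself.
#' @export
parameter_recovery <- function(variant, n_participants = 100L,
                               hyper = prior_hyper(), chains = 2L,
                               iter = 600L, warmup = 300L, seed = 1L,
                               backend = "mwg") {
  if (is.character(variant)) variant <- model_variant(variant)
  if (n_participants < 1) stop("n_participants must be >= 1")
  affective <- any(c("d_phi", "d_alpha_v", "lam") %in% variant$free)
  conds <- if (affective) c("positive", "neutral", "negative") else "neutral"
  npg <- stats::setNames(rep(ceiling(n_participants / length(conds)), length(conds)),
                         conds)
  coh <- simulate_cohort(npg, variant = variant, hyper = hyper,
                         seed = derive_seed(seed, 1L), conditions = conds)
  fit <- fit_hierarchical(coh, variant = variant, chains = chains, iter = iter,
                          warmup = warmup, seed = derive_seed(seed, 2L),
                          backend = backend)
  est <- participant_estimates(fit)
  truth <- coh$participants[match(est$participant_id, coh$participants$participant_id), ]
  rho <- vapply(variant$free, function(nm) {
    stats::cor(truth[[nm]], est[[nm]], method = "spearman")
  }, 0)
  merged <- est
  for (nm in variant$free) merged[[paste0(nm, "_true")]] <- truth[[nm]]
  structure(list(
    spearman = rho, estimates = merged, fit = fit,
    unconverged = as.integer(!fit$converged),
    settings = list(variant = variant$id, n_participants = n_participants,
                    chains = chains, iter = iter, warmup = warmup, seed = seed)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  if (!is.null(x$confusion)) {
    cat("confusion matrix (rows: generating, cols: selected):\n")
    print(x$confusion)
  }
  if (!is.null(x$spearman)) {
    cat("Spearman rho (true vs estimated):\n")
    print(round(x$spearman, 3))
  }
  if (x$unconverged > 0) cat("note:", x$unconverged, "fit(s) flagged unconverged\n")
  invisible(x)
}
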