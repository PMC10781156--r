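#' Assemble per-trial arrays for hierarchical fitting
#' @noRd
prep_fit_data <- function(trials, cues, phases) {
  use <- trials$phase %in% phases
  tr <- trials[use, , drop = FALSE]
  if (!nrow(tr)) stop("no trials in the requested phases")
  if (!all(tr$choice %in% c("left", "right"))) {
    stop("every modelled trial needs a choice of 'left' or 'right'")
  }
  ids <- unique(tr$participant_id)
  pid <- match(tr$participant_id, ids)
  d <- prep_choice_data(tr, cues)
  d$pid <- pid
  d$nP <- length(ids)
  d$ids <- ids
  d$aff <- tr$condition * d$aff_on
  d$y_left <- tr$choice == "left"
  d$obs <- tr[, intersect(c("participant_id", "condition", "phase", "block",
                            "trial_index", "trial_class"), names(tr))]
  d
}

#' Per-participant parameter vectors from state (free transformed, fixed rep)
#' @noRd
theta_from_state <- function(mu, sigma, z, free, fixed, nP) {
  th <- vector("list", 6L)
  names(th) <- param_names()
  for (nm in param_names()) {
    if (nm %in% free) {
      k <- match(nm, free)
      th[[nm]] <- transform_raw(mu[k] + sigma[k] * z[, k], nm)
    } else {
      th[[nm]] <- rep(fixed[[nm]], nP)
    }
  }
  th
}

#' One adaptive Metropolis-within-Gibbs chain with ASIS interweaving
#'
#' Non-centered participant updates (random-walk on the unit-normal z, one
#' free parameter at a time, all participants in parallel against the data)
#' alternate with centered group-level updates given the participant raw
#' values: a conjugate Gaussian draw for the group mean and a log-scale
#' random-walk step for the group SD (half-normal prior). The centered step
#' leaves the participant-level raw values — and hence the data likelihood —
#' untouched, so it costs no likelihood evaluations.
#' @noRd
run_mwg_chain <- function(d, free, fixed, iter, warmup, seed, chain_id) {
  set.seed(derive_seed(seed, chain_id))
  K <- length(free)
  nP <- d$nP
  mu <- stats::rnorm(K, 0, 0.3)
  sigma <- stats::runif(K, 0.3, 1)
  z <- matrix(stats::rnorm(nP * K, 0, 0.2), nP, K)
  s_z <- matrix(0.5, nP, K)
  s_s <- rep(0.3, K)
  th <- theta_from_state(mu, sigma, z, free, fixed, nP)
  th_t <- function(th) lapply(th, function(v) v[d$pid])
  ll_tr <- trial_loglik_core(th_t(th), d, d$aff, d$y_left)
  ll_i <- as.vector(rowsum(ll_tr, d$pid))

  n_keep <- iter - warmup
  p_cols <- unlist(lapply(free, function(nm) paste0(nm, "[", seq_len(nP), "]")))
  cols <- c(paste0("mu[", free, "]"), paste0("sigma[", free, "]"), p_cols)
  draws <- matrix(NA_real_, n_keep, length(cols), dimnames = list(NULL, cols))
  ll_keep <- matrix(NA_real_, n_keep, d$n)

  for (t in seq_len(iter)) {
    gam <- min(0.25, 2 / sqrt(t))
    for (k in seq_len(K)) {
      zk <- z[, k] + s_z[, k] * stats::rnorm(nP)
      thp <- th
      thp[[free[k]]] <- transform_raw(mu[k] + sigma[k] * zk, free[k])
      llp_tr <- trial_loglik_core(th_t(thp), d, d$aff, d$y_left)
      llp_i <- as.vector(rowsum(llp_tr, d$pid))
      logr <- (llp_i - ll_i) + 0.5 * (z[, k]^2 - zk^2)
      acc <- log(stats::runif(nP)) < logr
      if (any(acc)) {
        z[acc, k] <- zk[acc]
        th[[free[k]]][acc] <- thp[[free[k]]][acc]
        sel <- acc[d$pid]
        ll_tr[sel] <- llp_tr[sel]
        ll_i[acc] <- llp_i[acc]
      }
      if (t <= warmup) s_z[, k] <- s_z[, k] * exp(gam * (as.numeric(acc) - 0.44))
    }
    # ASIS: centered update of (mu, sigma) holding participant raws fixed
    for (k in seq_len(K)) {
      raw <- mu[k] + sigma[k] * z[, k]
      prec <- 1 + nP / sigma[k]^2
      mu[k] <- stats::rnorm(1, sum(raw) / sigma[k]^2 / prec, sqrt(1 / prec))
      lsp <- log(sigma[k]) + s_s[k] * stats::rnorm(1)
      sp <- max(exp(lsp), 1e-4)
      logr <- sum(stats::dnorm(raw, mu[k], sp, log = TRUE)) -
        sum(stats::dnorm(raw, mu[k], sigma[k], log = TRUE)) +
        stats::dnorm(sp, 0, 1, log = TRUE) - stats::dnorm(sigma[k], 0, 1, log = TRUE) +
        (log(sp) - log(sigma[k]))  # Jacobian of the log-scale proposal
      acc_s <- log(stats::runif(1)) < logr
      if (acc_s) sigma[k] <- sp
      if (t <= warmup) s_s[k] <- s_s[k] * exp(gam * (as.numeric(acc_s) - 0.30))
      z[, k] <- (raw - mu[k]) / sigma[k]
    }
    if (t > warmup) {
      i <- t - warmup
      draws[i, ] <- c(mu, sigma, unlist(th[free], use.names = FALSE))
      ll_keep[i, ] <- ll_tr
    }
  }
  list(draws = draws, loglik = ll_keep)
}

#' Build the BUGS model text for a variant (rjags backend)
#' @noRd
jags_model_text <- function(free, fixed) {
  node <- c(beta = "betaP", phi = "phicP", alpha_v = "alphaP",
            d_phi = "dphiP", d_alpha_v = "dalphaP", lam = "lamP")
  line <- function(nm) {
    if (nm %in% free) {
      k <- match(nm, free)
      raw <- sprintf("mu[%d] + sigma[%d]*z[i,%d]", k, k, k)
      switch(nm,
        beta = sprintf("    %s[i] <- phi(%s) * 50", node[nm], raw),
        phi = sprintf("    %s[i] <- phi(%s) * 10", node[nm], raw),
        lam = sprintf("    %s[i] <- phi(%s) * 10", node[nm], raw),
        sprintf("    %s[i] <- %s", node[nm], raw))
    } else {
      sprintf("    %s[i] <- %.10g", node[nm], fixed[[nm]])
    }
  }
  paste(c(
    "model {",
    "  for (k in 1:K) { mu[k] ~ dnorm(0, 1); sigma[k] ~ dnorm(0, 1) T(0,) }",
    "  for (i in 1:nP) {",
    "    for (k in 1:K) { z[i,k] ~ dnorm(0, 1) }",
    vapply(param_names(), line, ""),
    "  }",
    "  for (t in 1:nT) {",
    "    dec[t] <- pow(lamP[pid[t]], blk0[t]) * aff[t]",
    "    alE[t] <- alphaP[pid[t]] + dalphaP[pid[t]] * dec[t]",
    "    phE[t] <- phicP[pid[t]] + dphiP[pid[t]] * dec[t]",
    "    wL[t] <- ilogit(alE[t] * (vL1[t] - vL2[t]))",
    "    wR[t] <- ilogit(alE[t] * (vR1[t] - vR2[t]))",
    "    VL[t] <- (1 + (phE[t] - 1)*compL[t]) * (wL[t]*vL1[t] + (1 - wL[t])*vL2[t])",
    "    VR[t] <- (1 + (phE[t] - 1)*compR[t]) * (wR[t]*vR1[t] + (1 - wR[t])*vR2[t])",
    "    p[t] <- max(1.0E-12, min(1 - 1.0E-12, ilogit(betaP[pid[t]] * (VL[t] - VR[t]))))",
    "    y[t] ~ dbern(p[t])",
    "    loglik[t] <- y[t]*log(p[t]) + (1 - y[t])*log(1 - p[t])",
    "  }",
    "}"), collapse = "\n")
}

run_jags <- function(d, free, fixed, chains, iter, warmup, seed) {
  K <- length(free)
  dat <- list(K = K, nP = d$nP, nT = d$n, pid = d$pid,
              vL1 = d$vL1, vL2 = d$vL2, compL = d$compL,
              vR1 = d$vR1, vR2 = d$vR2, compR = d$compR,
              blk0 = d$blk0, aff = d$aff, y = as.integer(d$y_left))
  inits <- lapply(seq_len(chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = derive_seed(seed, c))
  })
  node <- c(beta = "betaP", phi = "phicP", alpha_v = "alphaP",
            d_phi = "dphiP", d_alpha_v = "dalphaP", lam = "lamP")
  monitors <- c("mu", "sigma", unname(node[free]), "loglik")
  m <- rjags::jags.model(textConnection(jags_model_text(free, fixed)), data = dat,
                         inits = inits, n.chains = chains, quiet = TRUE)
  stats::update(m, warmup, progress.bar = "none")
  s <- rjags::coda.samples(m, monitors, n.iter = iter - warmup,
                           progress.bar = "none")
  # rename to the native column scheme and split parameter / loglik columns
  rename <- function(cn) {
    cn <- sub("^mu\\[(\\d+)\\]$", "mu[@\\1]", cn)
    cn <- sub("^sigma\\[(\\d+)\\]$", "sigma[@\\1]", cn)
    for (k in seq_len(K)) {
      cn <- sub(sprintf("mu[@%d]", k), sprintf("mu[%s]", free[k]), cn, fixed = TRUE)
      cn <- sub(sprintf("sigma[@%d]", k), sprintf("sigma[%s]", free[k]), cn, fixed = TRUE)
    }
    for (nm in free) cn <- sub(paste0("^", node[nm], "\\["), paste0(nm, "["), cn)
    cn
  }
  per_chain <- lapply(s, function(ch) {
    mat <- as.matrix(ch)
    colnames(mat) <- rename(colnames(mat))
    is_ll <- grepl("^loglik\\[", colnames(mat))
    ll <- mat[, is_ll, drop = FALSE]
    ll <- ll[, order(as.integer(sub("^loglik\\[(\\d+)\\]$", "\\1", colnames(ll)))),
             drop = FALSE]
    list(draws = mat[, !is_ll, drop = FALSE], loglik = ll)
  })
  per_chain
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half; split-Rhat is the standard between/within
#' variance ratio over the resulting half-chains. Parameters with zero
#' within-chain variance return 1.
#'
#' @param x Matrix of draws (iterations x parameters) from one chain, or a
#'   list of such matrices (one per chain).
#' @return Named vector of split-Rhat values.
#' @export
split_rhat <- function(x) {
  if (is.matrix(x)) x <- list(x)
  halves <- list()
  for (ch in x) {
    n <- nrow(ch)
    h <- n %/% 2L
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(n - h + 1):n, , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(h) apply(h, 2, stats::var))
  if (is.null(dim(means))) { means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1) }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  rhat <- sqrt(((n - 1) / n * W + B / n) / W)
  rhat[!is.finite(rhat) | W < .Machine$double.eps] <- 1
  stats::setNames(rhat, colnames(x[[1]]))
}

#' Fit a model variant by hierarchical Bayesian MCMC
#'
#' Samples the joint posterior of group-level means/SDs and participant-level
#' parameters under the non-centered parameterization: each participant's raw
#' parameter is `mu + sigma * z`, `z ~ N(0, 1)`, transformed to its range via
#' [transform_raw()]. Priors are weakly informative: `mu ~ N(0, 1)`,
#' `sigma ~ half-N(0, 1)` on the raw scale. A single group-level Gaussian per
#' parameter covers all participants regardless of affect group (affect
#' enters only through the effective-parameter shift). Defaults follow the
#' replication configuration: 4 chains of 2750 iterations with 1500 warmup,
#' retaining 5000 draws.
#'
#' The default backend is the package's adaptive Metropolis-within-Gibbs
#' sampler with ancillarity-sufficiency interweaving (`"mwg"`); `"jags"`
#' runs the identical model in JAGS. A fit with any split-Rhat >= 1.1 is
#' tagged unconverged (never dropped silently).
#'
#' @param trials Trial table with `participant_id`, `condition` (-1/0/+1),
#'   `phase`, `block`, `is_baseline`, stimulus columns and `choice`; or a
#'   `cohort` object.
#' @param cues Cue set (taken from the cohort if omitted).
#' @param variant Model variant (object or id string).
#' @param chains,iter,warmup Sampler budget per chain (`iter` total, of which
#'   `warmup` discarded).
#' @param seed Integer seed; chain seeds are derived from it.
#' @param backend `"mwg"` (native) or `"jags"`.
#' @param phases Phases entering the likelihood.
#' @return An object of class `fit_result` with elements `draws` (retained
#'   draws x parameters, all chains stacked), `chain` (chain index per draw),
#'   `loglik` (draws x observations), `rhat`, `divergences`, `converged`,
#'   `variant`, `free`, `participants`, `obs` and `config`.
#' @export
fit_hierarchical <- function(trials, cues = NULL, variant = model_variant("4"),
                             chains = 4L, iter = 2750L, warmup = 1500L,
                             seed = 1L, backend = c("mwg", "jags"),
                             phases = c("simple_test", "generalization")) {
  if (inherits(trials, "cohort")) {
    cues <- trials$cues
    trials <- trials$trials
  }
  if (is.null(cues)) stop("cues must be supplied when trials is a data.frame")
  if (is.character(variant)) variant <- model_variant(variant)
  backend <- match.arg(backend)
  stopifnot(iter > warmup, chains >= 1)
  d <- prep_fit_data(trials, cues, phases)
  free <- variant$free
  fixed <- as.list(variant$fixed)
  res <- if (backend == "mwg") {
    lapply(seq_len(chains), function(c) {
      run_mwg_chain(d, free, fixed, iter, warmup, seed, c)
    })
  } else {
    run_jags(d, free, fixed, chains, iter, warmup, seed)
  }
  draw_list <- lapply(res, `[[`, "draws")
  # Rhat on group-level parameters and participant-level parameters alike
  rhat <- split_rhat(draw_list)
  draws <- do.call(rbind, draw_list)
  loglik <- do.call(rbind, lapply(res, `[[`, "loglik"))
  chain <- rep(seq_len(chains), each = iter - warmup)
  structure(list(
    draws = draws, chain = chain, loglik = loglik,
    rhat = rhat, divergences = 0L,
    converged = all(rhat < 1.1, na.rm = TRUE),
    variant = variant$id, free = free,
    participants = d$ids, obs = d$obs,
    config = list(chains = chains, iter = iter, warmup = warmup,
                  seed = seed, backend = backend, phases = phases)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> variant", x$variant, "|", length(x$participants),
      "participants,", ncol(x$loglik), "observations\n")
  cat("  ", nrow(x$draws), " retained draws (", x$config$chains, " chains x ",
      x$config$iter - x$config$warmup, "), backend ", x$config$backend, "\n", sep = "")
  cat("  max split-Rhat:", round(max(x$rhat, na.rm = TRUE), 3),
      if (x$converged) "(converged)" else "** NOT CONVERGED **", "\n")
  invisible(x)
}

#' Posterior medians of participant-level parameters
#'
#' @param fit A [fit_hierarchical()] result.
#' @return Data.frame with `participant_id` and one column per free
#'   parameter (posterior medians on the transformed scale).
#' @export
participant_estimates <- function(fit) {
  nP <- length(fit$participants)
  out <- data.frame(participant_id = fit$participants, stringsAsFactors = FALSE)
  for (nm in fit$free) {
    cols <- paste0(nm, "[", seq_len(nP), "]")
    out[[nm]] <- apply(fit$draws[, cols, drop = FALSE], 2, stats::median)
  }
  out
}

#' Widely Applicable Information Criterion from pointwise log-likelihoods
#'
#' `lppd_i = log mean_s exp(ll_si)` (computed log-sum-exp stably),
#' `p_i = Var_s(ll_si)` (sample variance over draws), and
#' `waic = -2 * (lppd - p_waic)` on the deviance scale (lower is better).
#'
#' @param loglik Matrix of pointwise log-likelihoods (draws x observations),
#'   or a `fit_result`.
#' @return List with `waic`, `lppd`, `p_waic`, `n_obs` and `pointwise`
#'   (per-observation `lppd_i`, `p_i`, `waic_i`).
#' @export
compute_waic <- function(loglik) {
  if (inherits(loglik, "fit_result")) loglik <- loglik$loglik
  if (!is.matrix(loglik) || nrow(loglik) < 2) stop("need a matrix with >= 2 draws")
  if (!all(is.finite(loglik))) stop("non-finite log-likelihood entries")
  S <- nrow(loglik)
  m <- apply(loglik, 2, max)
  lppd_i <- m + log(colMeans(exp(sweep(loglik, 2, m))))
  p_i <- apply(loglik, 2, stats::var)
  waic_i <- -2 * (lppd_i - p_i)
  list(waic = sum(waic_i), lppd = sum(lppd_i), p_waic = sum(p_i),
       n_obs = ncol(loglik),
       pointwise = data.frame(lppd_i = lppd_i, p_i = p_i, waic_i = waic_i))
}

#' Compare fitted model variants by WAIC
#'
#' Computes each model's WAIC (deviance scale), the difference to the
#' best-fitting (minimum-WAIC) model, and the standard error of each
#' difference from the pointwise contributions
#' (`SE = sqrt(n * Var_i(d_i))`, `d_i` the per-observation difference in
#' WAIC contributions). The selected model is the minimum-WAIC model unless
#' twice the SE of the difference to a rival overlaps zero, in which case the
#' tie is broken toward the model with fewer free parameters.
#'
#' @param fits List of [fit_hierarchical()] results over identical
#'   observations.
#' @return A `model_comparison` data.frame (one row per model: `model`,
#'   `n_free`, `waic`, `delta_waic`, `se_delta`, `selected`), with the
#'   selected variant id in attribute `"selected"`.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  n_obs <- vapply(fits, function(f) ncol(f$loglik), 0L)
  if (length(unique(n_obs)) != 1L) stop("fits cover different observation sets")
  n <- n_obs[1]
  w <- lapply(fits, compute_waic)
  waic <- vapply(w, `[[`, 0, "waic")
  best <- which.min(waic)
  delta <- waic - waic[best]
  se <- vapply(seq_along(fits), function(j) {
    if (j == best) return(NA_real_)
    d_i <- w[[j]]$pointwise$waic_i - w[[best]]$pointwise$waic_i
    sqrt(n * stats::var(d_i))
  }, 0)
  n_free <- vapply(fits, function(f) length(f$free), 0L)
  # tie set: models not credibly worse than the minimum-WAIC model
  tied <- delta == 0 | (!is.na(se) & delta < 2 * se)
  cand <- which(tied)
  sel <- cand[order(n_free[cand], waic[cand])][1]
  out <- data.frame(
    model = vapply(fits, `[[`, "", "variant"),
    n_free = n_free, waic = waic,
    delta_waic = delta, se_delta = se,
    selected = seq_along(fits) == sel,
    stringsAsFactors = FALSE
  )
  attr(out, "selected") <- out$model[sel]
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (WAIC, deviance scale; lower is better)\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  cat("selected:", attr(x, "selected"), "\n")
  invisible(x)
}

#' Summarize a posterior parameter
#'
#' @param fit A [fit_hierarchical()] result.
#' @param param Column name in the draws, e.g. `"mu[alpha_v]"` or
#'   `"beta[3]"`.
#' @param reference Reference value (0 for additive parameters, 1 for
#'   multiplicative ones); `prob_exceeds` is the fraction of draws above it.
#' @return List with `median`, `ci90` (central 90% credible interval) and
#'   `prob_exceeds`.
#' @export
posterior_summary <- function(fit, param, reference = 0) {
  draws <- if (inherits(fit, "fit_result")) fit$draws else as.matrix(fit)
  if (!param %in% colnames(draws)) stop("unknown parameter: ", param)
  x <- draws[, param]
  list(median = stats::median(x),
       ci90 = stats::quantile(x, c(0.05, 0.95), names = FALSE),
       prob_exceeds = mean(x > reference))
}
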