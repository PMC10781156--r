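test_that("attention weights follow the value-softmax and its limits", {
  expect_equal(attention_weights(0, c(0.25, 0.75)), c(0.5, 0.5))
  # scalar evaluation: A_2 = 1 / (1 + exp(-0.5))
  w <- attention_weights(1, c(0.25, 0.75))
  expect_equal(w[2], 1 / (1 + exp(-0.5)), tolerance = 1e-12)
  expect_equal(w[1], 1 - w[2], tolerance = 1e-12)
  # saturation without numerical blowup
  w_hi <- attention_weights(1000, c(0.25, 0.75))
  expect_equal(w_hi, c(0, 1), tolerance = 1e-10)
  expect_error(attention_weights(1, numeric(0)), "non-empty")
})

test_that("attention weights sum to one and are monotone in alpha_v", {
  withr::with_seed(99, {
    for (i in 1:50) {
      a <- rnorm(1, 0, 5)
      v <- runif(sample(2:4, 1), 0, 1)
      w <- attention_weights(a, v)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_true(all(w > 0 & w < 1))
    }
    # weight on the higher-value cue increases with alpha_v
    alphas <- sort(rnorm(10, 0, 4))
    w_h <- vapply(alphas, function(a) attention_weights(a, c(0.25, 0.75))[2], 0)
    expect_true(all(diff(w_h) > 0))
  })
})

test_that("stimulus values: empty 0, simple unscaled, compound phi-scaled average", {
  cues <- test_cues()
  cv <- cue_value_map(cues)
  m <- cue_of_class("M"); l <- cue_of_class("L"); h <- cue_of_class("H")
  expect_equal(stimulus_value(m, cv), 0.5)
  expect_equal(stimulus_value(m, cv, phi_eff = 2), 0.5)  # phi does not touch simples
  expect_equal(stimulus_value(character(0), cv, 2, 3), 0)
  expect_equal(stimulus_value(c(l, h), cv, 1, 0), 0.5)
  expect_equal(stimulus_value(c(l, h), cv, 1.5, 0), 0.75)
  expect_equal(stimulus_value(paste0(l, "+", h), cv, 1, 0), 0.5)  # string form
  expect_error(stimulus_value("nope", cv), "unknown cue")
  # with phi = 1 the compound value is a weighted average: stays in [min, max]
  withr::with_seed(4, {
    for (i in 1:25) {
      a <- rnorm(1, 0, 6)
      v <- stimulus_value(c(l, h), cv, 1, a)
      expect_gte(v, 0.25); expect_lte(v, 0.75)
    }
  })
})

test_that("effective parameters implement the power-law affect shift", {
  p <- list(beta = 10, phi = 1.2, alpha_v = -1, d_phi = -0.03,
            d_alpha_v = 0.68, lam = 0.45)
  # neutral reference: unchanged at any block
  e <- effective_params(p, affect = 0, block = 0:4)
  expect_equal(e$alpha_v_eff, rep(-1, 5))
  expect_equal(e$phi_eff, rep(1.2, 5))
  # first post-induction block gets the full shift (lam^0 = 1)
  e0 <- effective_params(p, affect = 1, block = 0)
  expect_equal(e0$alpha_v_eff, -0.32)
  # second block decays by lam: -1 + 0.68 * 0.45
  e1 <- effective_params(p, affect = 1, block = 1)
  expect_equal(e1$alpha_v_eff, -0.694)
  # pre-induction baseline: base parameters regardless of condition
  eb <- effective_params(p, affect = -1, block = 0, is_baseline = TRUE)
  expect_equal(eb$alpha_v_eff, -1)
  expect_equal(eb$phi_eff, 1.2)
  # lam = 1 makes the shift block-invariant
  p1 <- modifyList(p, list(lam = 1))
  eA <- effective_params(p1, 1, block = 0:5)
  expect_equal(diff(eA$alpha_v_eff), rep(0, 5))
  # lam = 0 with zero-indexed blocks: full effect in block 0, none later
  p0 <- modifyList(p, list(lam = 0))
  ez <- effective_params(p0, 1, block = 0:2)
  expect_equal(ez$alpha_v_eff, c(-0.32, -1, -1))
  expect_error(effective_params(p, 1, block = -1), "non-negative")
})

test_that("softmax choice probabilities are symmetric and bounded", {
  expect_equal(choice_prob(0.5, 0.5, 7)$p_left, 0.5)
  expect_equal(choice_prob(0.9, 0.1, 0)$p_left, 0.5)
  expect_equal(choice_prob(0.6, 0.5, 10)$p_left, 1 / (1 + exp(-1)), tolerance = 1e-12)
  a <- choice_prob(0.3, 0.8, 12)
  b <- choice_prob(0.8, 0.3, 12)
  expect_equal(a$p_left, b$p_right)
  expect_equal(a$p_left + a$p_right, 1)
  expect_error(choice_prob(1, 0, -1), "non-negative")
})

test_that("model variants free and fix the documented parameter subsets", {
  expect_equal(model_variant("1")$free, "beta")
  expect_equal(model_variant("1")$fixed[["phi"]], 1)
  expect_equal(model_variant("1")$fixed[["alpha_v"]], 0)
  expect_equal(model_variant("3")$fixed[["phi"]], 1)
  expect_setequal(model_variant("4c")$free,
                  c("beta", "phi", "alpha_v", "d_phi", "d_alpha_v"))
  expect_equal(model_variant("4c")$fixed[["lam"]], 1)
  expect_setequal(model_variant("4c_lam")$free,
                  c("beta", "phi", "alpha_v", "d_phi", "d_alpha_v", "lam"))
  expect_error(model_variant("5"), "unknown")
  expect_error(apply_variant(list(), model_variant("1")), "missing")
})

test_that("dataset log-likelihood matches a self-contained per-trial oracle", {
  cues <- test_cues()
  cv <- cue_value_map(cues)
  tr <- random_trials(1000, cues, seed = 21)
  params <- list(beta = 6, phi = 1.4, alpha_v = -1.2, d_phi = -0.05,
                 d_alpha_v = 0.7, lam = 0.5)
  affect <- -1
  got <- dataset_loglik(params, tr, cues, affect, variant = "4c_lam")
  # naive oracle: recompute every trial from the raw formulas
  oracle <- vapply(seq_len(nrow(tr)), function(i) {
    on <- tr$phase[i] == "generalization" && !tr$is_baseline[i]
    mult <- if (on) affect * params$lam^(max(tr$block[i] - 1, 0)) else 0
    al <- params$alpha_v + params$d_alpha_v * mult
    ph <- params$phi + params$d_phi * mult
    val <- function(s) {
      cl <- if (nzchar(s)) strsplit(s, "+", fixed = TRUE)[[1]] else character(0)
      if (!length(cl)) return(0)
      if (length(cl) == 1) return(unname(cv[cl]))
      e <- exp(al * cv[cl]); A <- e / sum(e)
      ph * sum(A * cv[cl])
    }
    vl <- val(tr$left_cues[i]); vr <- val(tr$right_cues[i])
    pl <- exp(params$beta * vl) / (exp(params$beta * vl) + exp(params$beta * vr))
    if (tr$choice[i] == "left") log(pl) else log(1 - pl)
  }, 0)
  expect_equal(got$pointwise, oracle, tolerance = 1e-10)
  expect_equal(got$total, sum(oracle), tolerance = 1e-10)
})

test_that("variant constraints are equivalent to fixing parameters in the full model", {
  cues <- test_cues()
  tr <- random_trials(60, cues, seed = 3)
  l1 <- dataset_loglik(list(beta = 9), tr, cues, 0, variant = "1")
  l4 <- dataset_loglik(list(beta = 9, phi = 1, alpha_v = 0), tr, cues, 0, variant = "4")
  expect_equal(l1$pointwise, l4$pointwise)
  # a single trial between equal-value options contributes log 0.5
  m <- cue_of_class("M"); m2 <- cue_of_class("M", 2)
  one <- data.frame(phase = "generalization", block = 1, trial_index = 1,
                    left_cues = m, right_cues = m2, trial_class = "x",
                    feedback = FALSE, is_baseline = FALSE, choice = "left",
                    stringsAsFactors = FALSE)
  expect_equal(dataset_loglik(list(beta = 5), one, cues, 0, "1")$total, log(0.5))
})

test_that("degenerate and extreme inputs are handled", {
  cues <- test_cues()
  bad <- data.frame(phase = "generalization", block = 1, trial_index = 1,
                    left_cues = "", right_cues = "", trial_class = "x",
                    feedback = FALSE, is_baseline = FALSE, choice = "left",
                    stringsAsFactors = FALSE)
  expect_error(dataset_loglik(list(beta = 5), bad, cues, 0, "1"), "empty")
  # likelihood stays finite at the beta bound with phi near its ceiling
  tr <- random_trials(200, cues, seed = 9)
  ll <- dataset_loglik(list(beta = 50, phi = 9.9, alpha_v = 30), tr, cues, 0, "4")
  expect_true(all(is.finite(ll$pointwise)))
})

test_that("raising alpha_v raises preference for the L/H compound on probes", {
  cues <- test_cues()
  cv <- cue_value_map(cues)
  l <- cue_of_class("L"); h <- cue_of_class("H")
  lh <- paste0(l, "+", h); mm <- paste0(cue_of_class("M"), "+", cue_of_class("M", 2))
  p_lh <- vapply(c(-4, -1, 0, 1, 4), function(a) {
    vl <- stimulus_value(lh, cv, 1, a)
    vr <- stimulus_value(mm, cv, 1, a)
    choice_prob(vl, vr, beta = 10)$p_left
  }, 0)
  expect_true(all(diff(p_lh) > 0))
  expect_equal(p_lh[3], 0.5)
})
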