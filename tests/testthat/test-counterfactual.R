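test_that("the design codes phoneme presence, not count, on audiovisual trials", {
  sim <- small_sim(seed = 19)
  scored <- score_trials(sim$trials, sim$lexicon, EQUIV)
  design <- build_design(scored)

  n_anv <- sum(scored$format %in% c("AnV_Real", "AnV_FACS", "AnV_DNN"))
  expect_equal(length(design$y), n_anv)
  expect_equal(nrow(design$presence), n_anv)
  expect_true(all(design$presence %in% c(0L, 1L)))

  # polish row: indicators exactly for {P, AA, L, IH, SH}
  i <- which(design$word == "polish")
  if (length(i) > 0) {
    on <- colnames(design$presence)[design$presence[i[1], ] == 1]
    expect_setequal(on, c("P", "AA", "L", "IH", "SH"))
  }
  # repeated phonemes still give an indicator of 1 (e.g. judge has two /JH/)
  j <- which(design$word == "judge")
  if (length(j) > 0) expect_equal(design$presence[j[1], "JH"], 1L)

  expect_equal(levels(design$face_class), c("real", "synthetic"))
  expect_equal(sum(design$face_class == "real"),
               sum(scored$format == "AnV_Real"))
})

test_that("the logistic fit recovers generating coefficients and calibrates", {
  # simulate directly from the model's own generative form: known betas,
  # random word-like presence patterns, Bernoulli outcomes
  set.seed(1234)
  n <- 5000L
  phonemes <- ARPABET[1:20]
  beta_real <- stats::setNames(rnorm(20, 0, 0.8), phonemes)
  beta_synth <- stats::setNames(rnorm(20, -0.4, 0.8), phonemes)
  presence <- matrix(rbinom(n * 39, 1, 0.25), n, 39,
                     dimnames = list(NULL, ARPABET))
  presence[, setdiff(ARPABET, phonemes)] <- 0L
  face <- factor(sample(c("real", "synthetic"), n, replace = TRUE),
                 levels = c("real", "synthetic"))
  eta <- ifelse(face == "real",
                0.3 + as.numeric(presence[, phonemes] %*% beta_real),
                -0.2 + as.numeric(presence[, phonemes] %*% beta_synth))
  y <- rbinom(n, 1, plogis(eta))
  design <- list(y = y, face_class = face, presence = presence,
                 word = apply(presence, 1, paste, collapse = ""))
  model <- fit_model(design)

  expect_false(model$stabilized)
  z_real <- abs(model$beta_real[phonemes] - beta_real) / model$se_real[phonemes]
  z_synth <- abs(model$beta_synthetic[phonemes] - beta_synth) /
    model$se_synthetic[phonemes]
  expect_gte(mean(c(z_real, z_synth) < 2), 0.90)

  # calibration-in-the-large per face class, within one percentage point
  for (fc in c("real", "synthetic")) {
    sel <- design$face_class == fc
    b <- if (fc == "real") model$beta_real else model$beta_synthetic
    ic <- if (fc == "real") model$intercept_real else model$intercept_synthetic
    pred <- plogis(ic + as.numeric(design$presence[sel, names(b)] %*% b))
    expect_lt(abs(mean(pred) - mean(y[sel])), 0.01)
  }
  expect_true(model$fit_r2 >= 0 && model$fit_r2 <= 1)
})

test_that("separation is stabilized rather than fatal", {
  sim <- small_sim(seed = 2, n_participants = 4,
                   transmission = flat_transmission(1))  # all correct
  scored <- score_trials(sim$trials, sim$lexicon, EQUIV)
  model <- suppressMessages(fit_model(build_design(scored)))
  expect_true(all(is.finite(model$beta_real)))
  expect_true(all(is.finite(model$beta_synthetic)))
})

test_that("counterfactual substitution behaves at its limits", {
  sim <- small_sim(seed = 23, n_participants = 12)
  scored <- score_trials(sim$trials, sim$lexicon, EQUIV)
  model <- suppressMessages(fit_model(build_design(scored)))

  # empty improved set: identity
  cf0 <- counterfactual_accuracy(model, character(0))
  expect_equal(cf0$counterfactual_accuracy, cf0$baseline_accuracy)

  # full substitution: synthetic trials predicted with real-face coefficients
  # plus the synthetic intercept
  all_ph <- names(model$beta_synthetic)
  cf_all <- counterfactual_accuracy(model, all_ph)
  synth <- model$design$face_class == "synthetic"
  pred_real <- plogis(model$intercept_synthetic + as.numeric(
    model$design$presence[synth, all_ph] %*% model$beta_real))
  expect_equal(cf_all$counterfactual_accuracy, mean(pred_real))

  # substitution is monotone when every improved coefficient increases
  better <- all_ph[model$beta_real > model$beta_synthetic]
  if (length(better) > 0) {
    cf <- counterfactual_accuracy(model, better)
    expect_gt(cf$counterfactual_accuracy, cf$baseline_accuracy)
  }
  expect_error(counterfactual_accuracy(model, "QQ"), "not in the model")
})

test_that("prevalence weighting reproduces its degenerate and linear limits", {
  sim <- small_sim(seed = 37, n_participants = 8)
  scored <- score_trials(sim$trials, sim$lexicon, EQUIV)
  rates <- count_identifications(scored)

  # uniform weights equal the unweighted mean of per-phoneme rates
  uni <- stats::setNames(rep(1, 39), ARPABET)
  ex <- suppressMessages(prevalence_extrapolation(rates, uni))
  expect_equal(unname(ex$predicted), unname(ex$actual))

  # weights concentrated on one phoneme return that phoneme's rate
  one <- stats::setNames(c(1, rep(0, 38)), c("T", setdiff(ARPABET, "T")))
  ex1 <- suppressMessages(prevalence_extrapolation(rates, one))
  t_real <- rates[rates$phoneme == "T" & rates$face_type == "Real", ]
  expect_equal(unname(ex1$predicted["Real"]),
               sum(t_real$n_identified) / sum(t_real$n_presented))

  # linearity: scaling all identification counts scales predictions
  half <- rates
  half$n_identified <- half$n_identified / 2
  half$rate <- half$rate / 2
  ex_half <- suppressMessages(prevalence_extrapolation(half, PREV))
  ex_full <- suppressMessages(prevalence_extrapolation(rates, PREV))
  expect_equal(unname(ex_half$predicted), unname(ex_full$predicted) / 2)
  expect_equal(ex_half$real_synthetic_difference,
               ex_full$real_synthetic_difference / 2)
})
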