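#' Build the phoneme-presence design for the word-accuracy logistic model
#'
#' One row per audiovisual trial (An and catch trials excluded), with the
#' binary word-correct outcome, a face class (`real` for AnV_Real,
#' `synthetic` for AnV_DNN and AnV_FACS pooled), and a 0/1 indicator per
#' phoneme marking whether the phoneme occurs at least once in the stimulus
#' word's phonemization (presence, not count).
#'
#' @param scored scored trial table from [score_trials()].
#' @return List with `y` (0/1 outcome), `face_class` (factor), `presence`
#'   (trials x 39 indicator matrix, columns named by phoneme), `word`
#'   (stimulus word per row).
#' @export
build_design <- function(scored) {
  phonemes <- attr(scored, "phonemes")
  if (is.null(phonemes)) stop("scored table lacks the phonemes attribute")
  keep <- which(scored$format %in% c("AnV_Real", "AnV_FACS", "AnV_DNN"))
  if (length(keep) == 0L) stop("no audiovisual trials in the table")
  presence <- t(vapply(keep, function(i) {
    as.integer(phoneme_counts(phonemes[[i]]$stimulus) > 0L)
  }, integer(length(ARPABET))))
  colnames(presence) <- ARPABET
  face_class <- factor(ifelse(scored$format[keep] == "AnV_Real",
                              "real", "synthetic"),
                       levels = c("real", "synthetic"))
  list(y = as.integer(scored$word_correct[keep]),
       face_class = face_class,
       presence = presence,
       word = scored$word[keep])
}

# expand the design into the model matrix: one intercept per face class and
# one presence column per face class x phoneme actually observed in that class
design_matrix <- function(design) {
  real <- design$face_class == "real"
  keep_ph <- colnames(design$presence)[
    colSums(design$presence[real, , drop = FALSE]) > 0 &
    colSums(design$presence[!real, , drop = FALSE]) > 0]
  Xr <- design$presence[, keep_ph, drop = FALSE] * as.numeric(real)
  Xs <- design$presence[, keep_ph, drop = FALSE] * as.numeric(!real)
  colnames(Xr) <- paste0("real_", keep_ph)
  colnames(Xs) <- paste0("synthetic_", keep_ph)
  X <- cbind(int_real = as.numeric(real), int_synthetic = as.numeric(!real),
             Xr, Xs)
  list(X = X, phonemes = keep_ph)
}

#' Fit the logistic phoneme-presence model of word accuracy
#'
#' Maximum-likelihood logistic regression of the word-correct outcome on
#' per-face-class phoneme-presence indicators: one coefficient per phoneme for
#' real-face trials, one per phoneme for synthetic-face trials, plus one
#' intercept per face class (needed for identifiability because presence
#' indicators are collinear across words). Phonemes not observed in both face
#' classes are dropped with a note. If the plain fit shows separation
#' (non-convergence or runaway coefficients), a ridge-stabilized refit at a
#' small fixed penalty is used instead and flagged.
#'
#' Model fit is summarized as `fit_r2`: the squared Pearson correlation
#' between observed per-word, per-face-class accuracy and the model's mean
#' predicted probability for the same cells (a logistic r-squared is otherwise
#' undefined; McFadden's pseudo r-squared is also reported).
#'
#' @param design design list from [build_design()].
#' @param ridge_lambda penalty used only for the stabilized refit.
#' @return Object of class `avsin_phoneme_model`: coefficient maps
#'   `beta_real`, `beta_synthetic`, intercepts, `fit_r2`, `mcfadden_r2`,
#'   `n_trials_fit`, `stabilized`, `dropped_phonemes`, plus the design.
#' @export
fit_model <- function(design, ridge_lambda = 1e-3) {
  dm <- design_matrix(design)
  dropped <- setdiff(colnames(design$presence), dm$phonemes)
  if (length(dropped) > 0L) {
    message("phonemes dropped (unseen in one face class): ",
            paste(dropped, collapse = ", "))
  }
  y <- design$y
  stabilized <- FALSE
  if (stats::var(y) == 0) {
    # degenerate all-correct / all-wrong outcome: no slope is identifiable;
    # report zero phoneme effects and a continuity-corrected intercept
    n <- length(y)
    ic <- stats::qlogis((sum(y) + 0.5) / (n + 1))
    dm0 <- design_matrix(design)
    ph <- dm0$phonemes
    zero <- stats::setNames(rep(0, length(ph)), ph)
    return(structure(list(
      beta_real = zero, beta_synthetic = zero,
      se_real = zero + NA_real_, se_synthetic = zero + NA_real_,
      intercept_real = ic, intercept_synthetic = ic,
      fit_r2 = NA_real_, mcfadden_r2 = NA_real_,
      n_trials_fit = n, stabilized = TRUE,
      dropped_phonemes = setdiff(colnames(design$presence), ph),
      design = design), class = "avsin_phoneme_model"))
  }
  fit <- suppressWarnings(
    stats::glm.fit(dm$X, y, family = stats::binomial()))
  beta <- fit$coefficients
  se <- rep(NA_real_, length(beta))
  names(se) <- names(beta)
  if (fit$converged && !anyNA(beta)) {
    # Wald standard errors from the weighted cross-product at the optimum
    w <- fit$weights
    XtWX <- crossprod(dm$X * sqrt(w))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(diag(cov))
  }
  if (!fit$converged || anyNA(beta) || any(abs(beta) > 15)) {
    stabilized <- TRUE
    gfit <- glmnet::glmnet(dm$X, y, family = "binomial", alpha = 0,
                           lambda = ridge_lambda, intercept = FALSE,
                           standardize = FALSE)
    beta <- as.numeric(gfit$beta)
    names(beta) <- rownames(gfit$beta)
    if (anyNA(beta) || any(!is.finite(beta))) {
      stop("logistic fit failed even after ridge stabilization; ",
           "n = ", length(y), ", mean(y) = ", mean(y))
    }
  }
  eta <- as.numeric(dm$X %*% beta)
  pred <- stats::plogis(eta)

  # calibration summaries on per-word x face-class cells
  cell <- paste(design$word, design$face_class, sep = "\r")
  obs <- tapply(y, cell, mean)
  hat <- tapply(pred, cell, mean)
  fit_r2 <- stats::cor(obs, hat)^2
  ll <- sum(y * log(pred) + (1 - y) * log(1 - pred))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  mcfadden <- 1 - ll / ll0

  ph <- dm$phonemes
  structure(list(
    beta_real = stats::setNames(beta[paste0("real_", ph)], ph),
    beta_synthetic = stats::setNames(beta[paste0("synthetic_", ph)], ph),
    se_real = stats::setNames(se[paste0("real_", ph)], ph),
    se_synthetic = stats::setNames(se[paste0("synthetic_", ph)], ph),
    intercept_real = unname(beta["int_real"]),
    intercept_synthetic = unname(beta["int_synthetic"]),
    fit_r2 = unname(fit_r2), mcfadden_r2 = mcfadden,
    n_trials_fit = length(y), stabilized = stabilized,
    dropped_phonemes = dropped, design = design),
    class = "avsin_phoneme_model")
}

#' @export
print.avsin_phoneme_model <- function(x, ...) {
  cat("Logistic phoneme-presence model of word accuracy\n")
  cat("  trials:", x$n_trials_fit,
      " phonemes:", length(x$beta_real),
      " fit r2:", round(x$fit_r2, 3),
      if (x$stabilized) " (ridge-stabilized)" else "", "\n")
  invisible(x)
}

predict_model <- function(model, face_class_beta, intercept, presence) {
  eta <- intercept + as.numeric(
    presence[, names(face_class_beta), drop = FALSE] %*% face_class_beta)
  stats::plogis(eta)
}

#' Counterfactual accuracy after substituting real-face coefficients
#'
#' Predicts mean word accuracy over the synthetic-face trials under the
#' fitted model (baseline), then again after replacing the synthetic-face
#' coefficient of every phoneme in `improved` with its real-face coefficient —
#' the hypothetical best case in which those phonemes are rendered as well as
#' on a real face.
#'
#' @param model fitted `avsin_phoneme_model`.
#' @param improved character vector of ARPAbet symbols to improve (empty set
#'   allowed: the counterfactual then equals the baseline).
#' @return List with `baseline_accuracy` and `counterfactual_accuracy`
#'   (fractions over synthetic trials).
#' @export
counterfactual_accuracy <- function(model, improved = c("TH", "DH", "F", "V")) {
  unknown <- setdiff(improved, names(model$beta_synthetic))
  if (length(unknown) > 0L) {
    stop("improved phonemes not in the model: ", paste(unknown, collapse = ", "))
  }
  synth <- model$design$face_class == "synthetic"
  presence <- model$design$presence[synth, , drop = FALSE]
  baseline <- mean(predict_model(model, model$beta_synthetic,
                                 model$intercept_synthetic, presence))
  beta_cf <- model$beta_synthetic
  beta_cf[improved] <- model$beta_real[improved]
  counterfactual <- mean(predict_model(model, beta_cf,
                                       model$intercept_synthetic, presence))
  list(baseline_accuracy = baseline, counterfactual_accuracy = counterfactual)
}

#' Load a phoneme-prevalence table
#'
#' Two-column delimited file mapping ARPAbet phonemes to relative frequencies
#' in the language at large. Weights are validated as nonnegative; they are
#' renormalized at use time over the phonemes shared with the rate data.
#'
#' @param path CSV path with columns `phoneme`, `weight` (header required).
#' @return Named numeric vector of weights.
#' @export
load_prevalence <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("phoneme", "weight") %in% names(tab)))
  w <- stats::setNames(tab$weight, toupper(tab$phoneme))
  if (any(w < 0)) stop("prevalence weights must be nonnegative")
  bad <- setdiff(names(w), ARPABET)
  if (length(bad) > 0L) stop("unknown phonemes in prevalence table: ",
                             paste(bad, collapse = ", "))
  w
}

#' Prevalence-weighted extrapolation to a large word corpus
#'
#' Predicts the phoneme accuracy an experiment would show if its stimulus
#' words matched the phoneme frequencies of the language at large: for each
#' condition (An, Real, Synthetic) the prediction is the prevalence-weighted
#' mean of the per-phoneme identification rates, with weights renormalized
#' over the phonemes present in both the prevalence table and the rate data.
#' The synthetic per-phoneme rate is the average of the DNN and FACS rates.
#'
#' @param rates rate table from [count_identifications()].
#' @param prevalence named weight vector from [load_prevalence()].
#' @return List with `predicted` (named: An, Real, Synthetic),
#'   `real_synthetic_difference`, `actual` (the same quantities under uniform
#'   weighting of the phonemes actually tested), `n_phonemes`, and
#'   `dropped` (phonemes present in rates but missing from the table).
#' @export
prevalence_extrapolation <- function(rates, prevalence) {
  per_ph_rate <- function(faces) {
    agg <- stats::aggregate(cbind(n_identified, n_presented) ~ phoneme,
                            data = rates[rates$face_type %in% faces, ],
                            FUN = sum)
    if (length(faces) > 1L) {
      # average of per-face pooled rates
      r <- sapply(faces, function(f) {
        a <- stats::aggregate(cbind(n_identified, n_presented) ~ phoneme,
                              data = rates[rates$face_type == f, ], FUN = sum)
        stats::setNames(a$n_identified / a$n_presented, a$phoneme)
      }, simplify = FALSE)
      common <- Reduce(intersect, lapply(r, names))
      rowMeans(sapply(r, function(v) v[common]))
    } else {
      stats::setNames(agg$n_identified / agg$n_presented, agg$phoneme)
    }
  }
  cond_rates <- list(An = per_ph_rate("An"),
                     Real = per_ph_rate("Real"),
                     Synthetic = per_ph_rate(c("DNN", "FACS")))
  common <- Reduce(intersect, c(lapply(cond_rates, names),
                                list(names(prevalence))))
  dropped <- setdiff(unique(rates$phoneme), common)
  if (length(dropped) > 0L) {
    message("phonemes dropped from extrapolation (missing in a condition or ",
            "the prevalence table): ", paste(dropped, collapse = ", "))
  }
  w <- prevalence[common]
  w <- w / sum(w)
  predicted <- vapply(cond_rates, function(r) sum(w * r[common]), numeric(1))
  actual <- vapply(cond_rates, function(r) mean(r[common]), numeric(1))
  list(predicted = predicted,
       real_synthetic_difference = unname(predicted["Real"] - predicted["Synthetic"]),
       actual = actual,
       actual_real_synthetic_difference = unname(actual["Real"] - actual["Synthetic"]),
       n_phonemes = length(common), dropped = dropped)
}
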