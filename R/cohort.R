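format_to_face <- function(format, face_type_for_catch = NULL) {
  face <- c(An = "An", AnV_Real = "Real", AnV_FACS = "FACS",
            AnV_DNN = "DNN")[format]
  if (!is.null(face_type_for_catch)) {
    catch <- format == "AV_catch"
    face[catch] <- face_type_for_catch[catch]
  }
  unname(face)
}

#' Per-participant condition summaries and grand means
#'
#' Computes mean word-level and phoneme-level accuracy per participant per
#' format, then averages the per-participant means across participants
#' (unweighted) to get the grand mean per format. Catch trials are summarized
#' under their own `AV_catch` label.
#'
#' @param scored scored trial table from [score_trials()].
#' @return List with `by_participant` (data frame: participant, format,
#'   mean_word_accuracy, mean_phoneme_accuracy, n_trials) and `grand` (data
#'   frame: format, word_accuracy, phoneme_accuracy, n_participants).
#' @export
summarize_conditions <- function(scored) {
  agg <- stats::aggregate(
    cbind(mean_word_accuracy = word_correct, mean_phoneme_accuracy = jaccard)
      ~ participant + format,
    data = scored, FUN = mean)
  cnt <- stats::aggregate(word_correct ~ participant + format,
                          data = scored, FUN = length)
  names(cnt)[3] <- "n_trials"
  by_part <- merge(agg, cnt, by = c("participant", "format"))
  by_part <- by_part[order(by_part$participant, by_part$format), ]
  rownames(by_part) <- NULL

  grand <- stats::aggregate(
    cbind(word_accuracy = mean_word_accuracy,
          phoneme_accuracy = mean_phoneme_accuracy) ~ format,
    data = by_part, FUN = mean)
  grand$n_participants <- stats::aggregate(
    participant ~ format, data = by_part,
    FUN = function(p) length(unique(p)))$participant
  list(by_participant = by_part, grand = grand)
}

#' Test the main effect of stimulus format on accuracy
#'
#' Fits a mixed-effects model of per-trial accuracy with a fixed effect of
#' word format and random intercepts for word, participant and participant
#' batch; the main effect is a likelihood-ratio test against the model without
#' format, and pairwise format contrasts are Tukey-adjusted estimated marginal
#' mean comparisons. Word-level accuracy uses a binomial model, phoneme-level
#' (Jaccard) accuracy a linear model on the fraction. Catch trials are
#' excluded.
#'
#' The `"fixed"` engine drops the random effects (ordinary `glm`/`lm` with the
#' same likelihood-ratio test); it is the documented fallback when variance
#' components degenerate or the mixed fit fails to converge, and the engine
#' used for large calibration simulations.
#'
#' @param scored scored trial table.
#' @param measure `"word"` or `"phoneme"`.
#' @param engine `"mixed"` (default) or `"fixed"`.
#' @return List with `chi_square`, `df`, `p_value`, `contrasts` (data frame of
#'   pairwise comparisons; `NULL` for the fixed engine), `engine`, `note`.
#' @export
test_format_effect <- function(scored, measure = c("word", "phoneme"),
                               engine = c("mixed", "fixed")) {
  measure <- match.arg(measure)
  engine <- match.arg(engine)
  dat <- scored[scored$format != "AV_catch", ]
  if (length(unique(dat$participant)) < 2L || length(unique(dat$format)) < 2L) {
    stop("need >= 2 participants and >= 2 formats")
  }
  dat$format <- factor(dat$format)
  dat$y <- if (measure == "word") as.numeric(dat$word_correct) else dat$jaccard

  note <- character(0)
  if (engine == "mixed") {
    fit <- tryCatch({
      if (measure == "word") {
        full <- lme4::glmer(
          y ~ format + (1 | word) + (1 | participant) + (1 | batch),
          data = dat, family = stats::binomial,
          control = lme4::glmerControl(calc.derivs = FALSE))
        null <- lme4::glmer(
          y ~ 1 + (1 | word) + (1 | participant) + (1 | batch),
          data = dat, family = stats::binomial,
          control = lme4::glmerControl(calc.derivs = FALSE))
      } else {
        full <- lme4::lmer(
          y ~ format + (1 | word) + (1 | participant) + (1 | batch),
          data = dat, REML = FALSE)
        null <- lme4::lmer(
          y ~ 1 + (1 | word) + (1 | participant) + (1 | batch),
          data = dat, REML = FALSE)
      }
      list(full = full, null = null)
    }, error = function(e) e, warning = function(w) w)
    if (inherits(fit, "condition")) {
      note <- paste("mixed fit degenerate, falling back to fixed effects:",
                    conditionMessage(fit))
      warning(note)
      engine <- "fixed"
    } else {
      lrt <- stats::anova(fit$null, fit$full)
      emm <- emmeans::emmeans(fit$full, "format")
      ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                             adjust = "tukey"))
      stat_col <- intersect(c("z.ratio", "t.ratio"), names(ctr))[1]
      contrasts <- data.frame(contrast = ctr$contrast,
                              estimate = ctr$estimate,
                              statistic = ctr[[stat_col]],
                              adjusted_p = ctr$p.value)
      return(list(chi_square = lrt$Chisq[2], df = lrt$Df[2],
                  p_value = lrt$`Pr(>Chisq)`[2],
                  contrasts = contrasts, engine = "mixed", note = note))
    }
  }
  # fixed-effects likelihood-ratio test
  if (measure == "word") {
    full <- stats::glm(y ~ format, data = dat, family = stats::binomial)
    null <- stats::glm(y ~ 1, data = dat, family = stats::binomial)
    chisq <- null$deviance - full$deviance
  } else {
    full <- stats::lm(y ~ format, data = dat)
    null <- stats::lm(y ~ 1, data = dat)
    n <- nrow(dat)
    chisq <- n * (log(sum(null$residuals^2)) - log(sum(full$residuals^2)))
  }
  df <- length(levels(dat$format)) - 1L
  list(chi_square = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
       contrasts = NULL, engine = "fixed", note = note)
}

#' Correlate visual-speech benefits across participants
#'
#' The benefit of a face format for a participant is that format's accuracy
#' minus the participant's auditory-only accuracy. `real_vs_synthetic`
#' correlates the real-face benefit with the synthetic benefit (mean of FACS
#' and DNN benefits); `dnn_vs_facs` correlates the two synthetic benefits.
#'
#' @param by_participant per-participant summary from [summarize_conditions()].
#' @param pairing `"real_vs_synthetic"` or `"dnn_vs_facs"`.
#' @param measure `"word"` or `"phoneme"`.
#' @return List with `r`, `p`, `n`, and the two benefit vectors.
#' @export
benefit_correlation <- function(by_participant,
                                pairing = c("real_vs_synthetic", "dnn_vs_facs"),
                                measure = c("word", "phoneme")) {
  pairing <- match.arg(pairing)
  measure <- match.arg(measure)
  col <- if (measure == "word") "mean_word_accuracy" else "mean_phoneme_accuracy"
  wide <- stats::reshape(
    by_participant[, c("participant", "format", col)],
    idvar = "participant", timevar = "format", direction = "wide")
  names(wide) <- sub(paste0("^", col, "\\."), "", names(wide))
  need <- c("An", "AnV_Real", "AnV_FACS", "AnV_DNN")
  wide <- wide[stats::complete.cases(wide[, intersect(need, names(wide))]), ]
  if (nrow(wide) < 3L) stop("need >= 3 participants with all formats")

  if (pairing == "real_vs_synthetic") {
    x <- wide$AnV_Real - wide$An
    y <- (wide$AnV_FACS + wide$AnV_DNN) / 2 - wide$An
  } else {
    x <- wide$AnV_DNN - wide$An
    y <- wide$AnV_FACS - wide$An
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate benefit vector")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(wide),
       benefit_a = x, benefit_b = y)
}
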