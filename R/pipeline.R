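#' Validate pipeline inputs
#'
#' Checks that the lexicon parses, the trial table has the required schema,
#' format labels are recognisable (case differences are normalized with a
#' warning), and every stimulus word is phonemizable from the lexicon.
#'
#' @param trials trial data frame.
#' @param lexicon an `avsin_lexicon`.
#' @return Invisibly TRUE; stops with a message naming the offending word or
#'   column on failure.
#' @export
validate_inputs <- function(trials, lexicon) {
  req <- c("participant", "batch", "word", "format", "response")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols) > 0L) {
    stop("trial table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  fmt_idx <- match(tolower(trials$format), tolower(TRIAL_FORMATS))
  if (anyNA(fmt_idx)) {
    stop("unknown format label(s): ",
         paste(unique(trials$format[is.na(fmt_idx)]), collapse = ", "))
  }
  if (any(TRIAL_FORMATS[fmt_idx] != trials$format)) {
    warning("format labels differ from canonical spelling only by case; ",
            "they will be normalized")
  }
  if (any(!nzchar(trimws(trials$response)))) stop("empty response(s) in trial table")
  oov <- setdiff(unique(normalize_response(trials$word)), names(lexicon$entries))
  if (length(oov) > 0L) {
    stop("stimulus word(s) missing from lexicon: ", paste(oov, collapse = ", "))
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Scores a trial table and runs every downstream analysis: condition
#' summaries, the format main-effect test, benefit correlations, per-phoneme
#' rates and difference tables, the four-phoneme group contrast, the logistic
#' phoneme-presence model with its counterfactual substitution, the
#' prevalence-weighted extrapolation (if a prevalence table is supplied) and
#' the paired-t power calculations. Optionally writes every table under
#' `out_dir` as CSV/JSON.
#'
#' @param trials trial data frame (e.g. from [simulate_experiment()] or read
#'   from a delimited file).
#' @param lexicon an `avsin_lexicon`.
#' @param equivalences misspelling-equivalence table.
#' @param prevalence optional named prevalence weights.
#' @param improved phonemes improved in the counterfactual.
#' @param engine engine for [test_format_effect()].
#' @param out_dir optional output directory (created if needed).
#' @return List of class `avsin_report` with components `scored`, `summary`,
#'   `format_effect_word`, `format_effect_phoneme`, `benefit`, `rates`,
#'   `real_synthetic`, `dnn_facs`, `group_contrast`, `model`,
#'   `counterfactual`, `extrapolation`, `power`, `log`.
#' @export
run_pipeline <- function(trials, lexicon,
                         equivalences = load_equivalences(),
                         prevalence = NULL,
                         improved = c("TH", "DH", "F", "V"),
                         engine = c("mixed", "fixed"),
                         out_dir = NULL) {
  engine <- match.arg(engine)
  validate_inputs(trials, lexicon)

  scored <- score_trials(trials, lexicon, equivalences)
  summary <- summarize_conditions(scored)
  fe_word <- test_format_effect(scored, "word", engine)
  fe_phon <- test_format_effect(scored, "phoneme", engine)
  benefit <- lapply(c(word = "word", phoneme = "phoneme"), function(m) {
    tryCatch(benefit_correlation(summary$by_participant,
                                 "real_vs_synthetic", m),
             error = function(e) list(error = conditionMessage(e)))
  })
  rates <- count_identifications(scored)
  rs <- real_synthetic_differences(rates)
  df <- dnn_vs_facs(rates)
  gc <- group_contrast(rates, improved)
  model <- fit_model(build_design(scored))
  improved_avail <- intersect(improved, names(model$beta_synthetic))
  if (length(improved_avail) < length(improved)) {
    message("improved phonemes not in the fitted model, skipped: ",
            paste(setdiff(improved, improved_avail), collapse = ", "))
  }
  cf <- counterfactual_accuracy(model, improved_avail)
  extrap <- if (!is.null(prevalence)) {
    prevalence_extrapolation(rates, prevalence)
  }
  power <- list(
    conservative = c(list(d = 0.5, alpha = 0.0167, target_power = 0.90),
                     required_n(0.5, 0.0167, 0.90)),
    pilot = c(list(d = 1.68, alpha = 0.05, target_power = 0.90),
              required_n(1.68, 0.05, 0.90)))

  log <- list(n_trials = nrow(scored),
              n_oov_responses = sum(scored$oov_flag),
              n_equivalence_hits = sum(scored$word_correct &
                normalize_response(scored$word) != normalize_response(scored$response)))

  report <- structure(list(
    scored = scored, summary = summary,
    format_effect_word = fe_word, format_effect_phoneme = fe_phon,
    benefit = benefit, rates = rates, real_synthetic = rs, dnn_facs = df,
    group_contrast = gc, model = model, counterfactual = cf,
    extrapolation = extrap, power = power, log = log),
    class = "avsin_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE)
  scored <- report$scored
  attr(scored, "phonemes") <- NULL
  w(scored, "scored_trials.csv")
  w(report$summary$by_participant, "condition_summary_by_participant.csv")
  w(report$summary$grand, "condition_summary_grand.csv")
  w(report$rates, "phoneme_rates.csv")
  w(report$real_synthetic, "real_synthetic_differences.csv")
  w(report$dnn_facs, "dnn_vs_facs_differences.csv")
  w(report$group_contrast, "group_contrast.csv")
  coefs <- data.frame(phoneme = names(report$model$beta_real),
                      beta_real = unname(report$model$beta_real),
                      beta_synthetic = unname(report$model$beta_synthetic))
  w(coefs, "model_coefficients.csv")
  fe <- function(x) x[c("chi_square", "df", "p_value", "engine")]
  jsonlite::write_json(
    list(format_effect = list(word = fe(report$format_effect_word),
                              phoneme = fe(report$format_effect_phoneme)),
         model = list(fit_r2 = report$model$fit_r2,
                      mcfadden_r2 = report$model$mcfadden_r2,
                      n_trials = report$model$n_trials_fit,
                      stabilized = report$model$stabilized),
         counterfactual = report$counterfactual,
         extrapolation = report$extrapolation,
         power = report$power,
         log = report$log),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.avsin_report <- function(x, ...) {
  cat("Audiovisual speech-in-noise analysis report\n")
  cat(" trials scored:", x$log$n_trials,
      " (OOV-fallback responses:", paste0(x$log$n_oov_responses, ")\n"))
  g <- x$summary$grand
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-9s word %5.1f%%  phoneme %5.1f%%\n", g$format[i],
                100 * g$word_accuracy[i], 100 * g$phoneme_accuracy[i]))
  }
  cat(sprintf(" format main effect (word): chi2_%d = %.1f, p = %.3g [%s]\n",
              x$format_effect_word$df, x$format_effect_word$chi_square,
              x$format_effect_word$p_value, x$format_effect_word$engine))
  cat(sprintf(" model fit r2 = %.3f; counterfactual %.1f%% vs baseline %.1f%%\n",
              x$model$fit_r2, 100 * x$counterfactual$counterfactual_accuracy,
              100 * x$counterfactual$baseline_accuracy))
  invisible(x)
}
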