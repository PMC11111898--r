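#' Count per-phoneme identifications by participant and face type
#'
#' For every trial and every distinct phoneme in the stimulus, the number of
#' identified occurrences is the minimum of the phoneme's multiplicity in the
#' stimulus and in the response (the same min-multiplicity rule as the Jaccard
#' intersection), and the number of presented occurrences is its multiplicity
#' in the stimulus. Counts are accumulated per participant x face type
#' (An, Real, FACS, DNN); catch trials are excluded.
#'
#' @param scored scored trial table from [score_trials()] (must carry the
#'   `phonemes` attribute).
#' @return Data frame with columns `phoneme`, `face_type`, `participant`,
#'   `n_identified`, `n_presented`, `rate`; only cells with
#'   `n_presented > 0` appear.
#' @export
count_identifications <- function(scored) {
  phonemes <- attr(scored, "phonemes")
  if (is.null(phonemes)) stop("scored table lacks the phonemes attribute")
  keep <- which(scored$format != "AV_catch")
  face <- format_to_face(scored$format)

  # accumulate 39-vector counts into participant x face cells
  acc <- new.env(parent = emptyenv())
  for (i in keep) {
    key <- paste0(scored$participant[i], "\r", face[i])
    cell <- acc[[key]]
    if (is.null(cell)) {
      cell <- list(pres = integer(length(ARPABET)),
                   ident = integer(length(ARPABET)))
    }
    sc <- phoneme_counts(phonemes[[i]]$stimulus)
    rc <- phoneme_counts(phonemes[[i]]$response)
    cell$pres <- cell$pres + sc
    cell$ident <- cell$ident + pmin(sc, rc)
    acc[[key]] <- cell
  }
  keys <- ls(acc)
  rows <- lapply(keys, function(key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    cell <- acc[[key]]
    idx <- which(cell$pres > 0L)
    data.frame(phoneme = ARPABET[idx],
               face_type = parts[2],
               participant = parts[1],
               n_identified = cell$ident[idx],
               n_presented = cell$pres[idx])
  })
  out <- do.call(rbind, rows)
  out$rate <- out$n_identified / out$n_presented
  out <- out[order(out$phoneme, out$face_type, out$participant), ]
  rownames(out) <- NULL
  out
}

# pool counts for one phoneme x face set across participants
pool_counts <- function(rates, phoneme, faces) {
  sub <- rates[rates$phoneme == phoneme & rates$face_type %in% faces, ]
  c(identified = sum(sub$n_identified), presented = sum(sub$n_presented))
}

two_prop_z <- function(x1, n1, x2, n2) {
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  if (se == 0) return(1)
  z <- (x1 / n1 - x2 / n2) / se
  2 * stats::pnorm(-abs(z))
}

# per-phoneme aggregated rate and two-condition test, either on pooled counts
# (two-proportion z) or via a binomial GLMM with participant random intercept
# (Wald test on the condition coefficient)
phoneme_condition_test <- function(rates, phoneme, faces_a, faces_b,
                                   method = c("pooled", "glmm")) {
  method <- match.arg(method)
  a <- pool_counts(rates, phoneme, faces_a)
  b <- pool_counts(rates, phoneme, faces_b)
  if (a["presented"] == 0L || b["presented"] == 0L) return(NULL)
  # condition rate = mean of the per-face-type pooled rates, so that the
  # synthetic rate is the average of DNN and FACS, not a trial-weighted pool
  rate_face <- function(faces) {
    r <- vapply(faces, function(f) {
      cnt <- pool_counts(rates, phoneme, f)
      if (cnt["presented"] == 0L) NA_real_ else cnt["identified"] / cnt["presented"]
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }
  rate_a <- rate_face(faces_a)
  rate_b <- rate_face(faces_b)

  if (method == "glmm") {
    sub <- rates[rates$phoneme == phoneme & rates$face_type %in% c(faces_a, faces_b), ]
    sub$cond <- factor(ifelse(sub$face_type %in% faces_a, "a", "b"),
                       levels = c("b", "a"))
    p <- tryCatch({
      fit <- lme4::glmer(
        cbind(n_identified, n_presented - n_identified) ~ cond + (1 | participant),
        data = sub, family = stats::binomial,
        control = lme4::glmerControl(calc.derivs = FALSE))
      stats::coef(summary(fit))["conda", "Pr(>|z|)"]
    }, error = function(e) NA_real_, warning = function(w) NA_real_)
    if (is.na(p)) {
      p <- two_prop_z(a["identified"], a["presented"], b["identified"], b["presented"])
    }
  } else {
    p <- two_prop_z(a["identified"], a["presented"], b["identified"], b["presented"])
  }
  list(rate_a = rate_a, rate_b = rate_b, p = unname(p))
}

phoneme_difference_table <- function(rates, faces_a, faces_b,
                                     method = "pooled", alpha = 0.05) {
  tested <- intersect(ARPABET, unique(rates$phoneme))
  rows <- lapply(tested, function(ph) {
    res <- phoneme_condition_test(rates, ph, faces_a, faces_b, method)
    if (is.null(res)) return(NULL)
    data.frame(phoneme = ph, rate_a = res$rate_a, rate_b = res$rate_b,
               difference = res$rate_a - res$rate_b, p = res$p)
  })
  out <- do.call(rbind, rows)
  # Bonferroni family = the full canonical phoneme set
  out$adjusted_p <- pmin(1, out$p * length(ARPABET))
  out$significant <- out$adjusted_p < alpha
  out <- out[order(-out$difference), ]
  rownames(out) <- NULL
  out
}

#' Per-phoneme real-minus-synthetic accuracy differences
#'
#' For each phoneme, aggregates identification rates across participants for
#' real faces and for synthetic faces (the synthetic rate is the average of
#' the DNN and FACS rates), takes the real - synthetic difference, and tests
#' it with Bonferroni correction across the 39-phoneme family. The default
#' test is a two-proportion z on pooled counts; `method = "glmm"` instead fits
#' a per-phoneme binomial model with a participant random intercept and uses
#' the Wald test on the face-type coefficient (reverting to pooled counts for
#' phonemes where that fit degenerates). The table is sorted by descending
#' difference.
#'
#' @param rates rate table from [count_identifications()].
#' @param method `"pooled"` (default) or `"glmm"`.
#' @param alpha family-wise significance level.
#' @return Data frame: `phoneme`, `real_rate`, `synthetic_rate`, `difference`,
#'   `p`, `adjusted_p`, `significant`, sorted by descending difference.
#' @export
real_synthetic_differences <- function(rates, method = c("pooled", "glmm"),
                                       alpha = 0.05) {
  method <- match.arg(method)
  out <- phoneme_difference_table(rates, "Real", c("DNN", "FACS"),
                                  method, alpha)
  names(out)[names(out) == "rate_a"] <- "real_rate"
  names(out)[names(out) == "rate_b"] <- "synthetic_rate"
  out
}

#' Per-phoneme DNN-minus-FACS accuracy differences
#'
#' Same construction and correction family as
#' [real_synthetic_differences()], comparing the two synthetic face types.
#' Positive differences mean higher accuracy for DNN faces.
#'
#' @inheritParams real_synthetic_differences
#' @return Data frame: `phoneme`, `dnn_rate`, `facs_rate`, `difference`, `p`,
#'   `adjusted_p`, `significant`.
#' @export
dnn_vs_facs <- function(rates, method = c("pooled", "glmm"), alpha = 0.05) {
  method <- match.arg(method)
  out <- phoneme_difference_table(rates, "DNN", "FACS", method, alpha)
  names(out)[names(out) == "rate_a"] <- "dnn_rate"
  names(out)[names(out) == "rate_b"] <- "facs_rate"
  out
}

#' Paired contrast of a phoneme group against all other phonemes
#'
#' For a phoneme group of interest (by default the dental and labiodental
#' fricatives /TH DH F V/, whose diagnostic visual features synthetic faces
#' tend to miss), each participant contributes a mean identification rate for
#' the group and for the remaining phonemes; a paired-samples t-test compares
#' the two across participants. Run separately within the Real condition, the
#' Synthetic condition (DNN and FACS pooled), and on the per-participant
#' real - synthetic difference.
#'
#' @param rates rate table from [count_identifications()].
#' @param group character vector of ARPAbet symbols forming the group.
#' @return Data frame with one row per condition (`Real`, `Synthetic`,
#'   `Difference`): group and rest means, `t`, `df`, `p`, `n` participants.
#' @export
group_contrast <- function(rates, group = c("TH", "DH", "F", "V")) {
  stopifnot(all(group %in% ARPABET))
  part_means <- function(faces) {
    sub <- rates[rates$face_type %in% faces, ]
    # per-participant, per-phoneme rate (counts pooled over the faces), then
    # unweighted mean over group / non-group phonemes
    agg <- stats::aggregate(cbind(n_identified, n_presented)
                            ~ participant + phoneme, data = sub, FUN = sum)
    agg$rate <- agg$n_identified / agg$n_presented
    agg$in_group <- agg$phoneme %in% group
    m <- stats::aggregate(rate ~ participant + in_group, data = agg, FUN = mean)
    wide <- stats::reshape(m, idvar = "participant", timevar = "in_group",
                           direction = "wide")
    names(wide)[names(wide) == "rate.FALSE"] <- "rest"
    names(wide)[names(wide) == "rate.TRUE"] <- "grp"
    if (!all(c("rest", "grp") %in% names(wide))) {
      stop("group or rest phonemes absent from the rate table")
    }
    wide[stats::complete.cases(wide), ]
  }
  real <- part_means("Real")
  synth <- part_means(c("DNN", "FACS"))

  one_test <- function(grp, rest, label) {
    if (length(grp) < 3L) stop("need >= 3 participants with both group means")
    tt <- stats::t.test(grp, rest, paired = TRUE)
    data.frame(condition = label, group_mean = mean(grp), rest_mean = mean(rest),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n = length(grp))
  }
  common <- intersect(real$participant, synth$participant)
  r <- real[match(common, real$participant), ]
  s <- synth[match(common, synth$participant), ]
  rbind(one_test(r$grp, r$rest, "Real"),
        one_test(s$grp, s$rest, "Synthetic"),
        one_test(r$grp - s$grp, r$rest - s$rest, "Difference"))
}
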