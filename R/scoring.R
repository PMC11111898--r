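#' Multiset Jaccard overlap between two phoneme sequences
#'
#' The phoneme-level accuracy measure: the number of phonemes in common
#' between stimulus and response divided by the total number of phonemes in
#' both. Repeated phonemes count with their multiplicity, so the intersection
#' is the sum over distinct symbols of the minimum count in the two sequences,
#' and the union is `|stim| + |resp| - intersection`.
#'
#' @param stim,resp character vectors of stress-stripped ARPAbet symbols.
#' @return List with `jaccard`, `n_intersection`, `n_union`.
#' @examples
#' jaccard_overlap(c("P","AA","L","IH","SH"), c("P","AA","L","AH","S","IY"))
#' # jaccard 3/8 = 0.375
#' @export
jaccard_overlap <- function(stim, resp) {
  if (length(stim) < 1L || length(resp) < 1L) {
    stop("phoneme sequences must be non-empty")
  }
  n_int <- sum(pmin(phoneme_counts(stim), phoneme_counts(resp)))
  n_union <- length(stim) + length(resp) - n_int
  list(jaccard = n_int / n_union, n_intersection = n_int, n_union = n_union)
}

#' Load a curated misspelling-equivalence table
#'
#' Two-column CSV (`stimulus`, `response`) of word pairs accepted as correct
#' even though they are neither exact matches nor homophones — accepted
#' misspellings such as echos/echoes. Matching is symmetric and applied after
#' normalization.
#'
#' @param path CSV path; `NULL` returns the empty table.
#' @return Data frame with columns `stimulus`, `response`.
#' @export
load_equivalences <- function(path = NULL) {
  if (is.null(path)) {
    return(data.frame(stimulus = character(0), response = character(0)))
  }
  eq <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("stimulus", "response") %in% names(eq)))
  eq$stimulus <- normalize_response(eq$stimulus)
  eq$response <- normalize_response(eq$response)
  eq
}

in_equivalences <- function(stimulus, response, equivalences) {
  if (nrow(equivalences) == 0L) return(FALSE)
  any((equivalences$stimulus == stimulus & equivalences$response == response) |
      (equivalences$stimulus == response & equivalences$response == stimulus))
}

#' Score a response at the word level
#'
#' A trial is correct iff the normalized response equals the normalized
#' stimulus, the two words are homophones, or the pair appears in the curated
#' equivalence table of accepted misspellings. Always returns a boolean.
#'
#' @param stimulus stimulus word (must be in the lexicon).
#' @param response typed free-text response.
#' @param lexicon an `avsin_lexicon`.
#' @param equivalences equivalence table from [load_equivalences()].
#' @return Logical scalar.
#' @export
score_word <- function(stimulus, response, lexicon,
                       equivalences = load_equivalences()) {
  ns <- normalize_response(stimulus)
  nr <- normalize_response(response)
  if (!nzchar(nr)) return(FALSE)
  if (ns == nr) return(TRUE)
  if (in_equivalences(ns, nr, equivalences)) return(TRUE)
  # homophone check only meaningful for single-token in-lexicon responses
  if (!grepl(" ", nr, fixed = TRUE) && !is.null(lexicon$entries[[nr]])) {
    if (suppressWarnings(are_homophones(ns, nr, lexicon))) return(TRUE)
  }
  FALSE
}

#' Score one trial at word and phoneme level
#'
#' Combines binary word scoring with the multiset Jaccard phoneme measure.
#' The Jaccard index is maximized over all stimulus-variant x response-variant
#' pronunciation pairs (a deterministic rule that is lenient in the same
#' direction as manual scoring, and whose maximum is unique). Trials judged
#' word-correct through the homophone or misspelling route are given full
#' phoneme credit (jaccard = 1).
#'
#' @param stimulus stimulus word.
#' @param response typed response text.
#' @param lexicon an `avsin_lexicon`.
#' @param equivalences equivalence table.
#' @return List: `word_correct`, `jaccard`, `n_intersection`, `n_union`,
#'   `stimulus_phonemes`, `response_phonemes`, `oov_flag`.
#' @export
score_trial <- function(stimulus, response, lexicon,
                        equivalences = load_equivalences()) {
  stim_ph <- phonemize(stimulus, lexicon)
  resp_ph <- phonemize(response, lexicon)
  word_correct <- score_word(stimulus, response, lexicon, equivalences)

  best <- NULL
  for (sv in stim_ph$variants) for (rv in resp_ph$variants) {
    j <- jaccard_overlap(sv, rv)
    if (is.null(best) || j$jaccard > best$jaccard) {
      best <- c(j, list(stim = sv, resp = rv))
    }
  }
  if (word_correct) {
    # full phoneme credit propagates from the lenient word-level judgement
    sv <- best$stim
    best <- list(jaccard = 1, n_intersection = length(sv),
                 n_union = length(sv), stim = sv, resp = sv)
  }
  list(word_correct = word_correct,
       jaccard = best$jaccard,
       n_intersection = best$n_intersection,
       n_union = best$n_union,
       stimulus_phonemes = best$stim,
       response_phonemes = best$resp,
       oov_flag = stim_ph$oov || resp_ph$oov)
}

TRIAL_FORMATS <- c("An", "AnV_Real", "AnV_FACS", "AnV_DNN", "AV_catch")

#' Score a full trial table
#'
#' Applies [score_trial()] to every row of a trial table (columns
#' `participant`, `batch`, `word`, `format`, `response`, and optionally
#' `face_type_for_catch`). Format labels are matched case-insensitively and
#' normalized to the canonical spelling with a warning.
#'
#' @param trials data frame of trials.
#' @param lexicon an `avsin_lexicon`.
#' @param equivalences equivalence table.
#' @return The input data frame with appended columns `word_correct`,
#'   `jaccard`, `n_intersection`, `n_union`, `oov_flag`, plus attribute
#'   `phonemes`: a list of per-trial `list(stimulus, response)` phoneme
#'   sequences used by the phoneme-specific analysis.
#' @export
score_trials <- function(trials, lexicon, equivalences = load_equivalences()) {
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
  canon <- TRIAL_FORMATS[fmt_idx]
  if (any(canon != trials$format)) {
    warning("non-canonical format labels normalized (case differences)")
    trials$format <- canon
  }

  n <- nrow(trials)
  word_correct <- logical(n)
  jac <- numeric(n)
  n_int <- integer(n)
  n_un <- integer(n)
  oov <- logical(n)
  phonemes <- vector("list", n)
  # responses repeat heavily across trials; memoize on (stimulus, response)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    key <- paste0(trials$word[i], "\r", trials$response[i])
    s <- cache[[key]]
    if (is.null(s)) {
      s <- score_trial(trials$word[i], trials$response[i], lexicon, equivalences)
      cache[[key]] <- s
    }
    word_correct[i] <- s$word_correct
    jac[i] <- s$jaccard
    n_int[i] <- s$n_intersection
    n_un[i] <- s$n_union
    oov[i] <- s$oov_flag
    phonemes[[i]] <- list(stimulus = s$stimulus_phonemes,
                          response = s$response_phonemes)
  }
  out <- trials
  out$word_correct <- word_correct
  out$jaccard <- jac
  out$n_intersection <- n_int
  out$n_union <- n_un
  out$oov_flag <- oov
  attr(out, "phonemes") <- phonemes
  out
}
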