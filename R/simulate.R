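#' Load a phoneme-to-viseme map
#'
#' Two-column CSV mapping each of the 39 ARPAbet phonemes to a viseme class
#' (a set of mouth configurations indistinguishable to a viewer). The packaged
#' default is a standard English grouping in which the labiodental fricatives
#' {F, V} and the dental fricatives {TH, DH} each form their own class; no
#' universally agreed map exists, so the map is replaceable.
#'
#' @param path CSV with columns `phoneme`, `viseme`; default is the packaged
#'   map.
#' @return Named character vector: viseme class per phoneme, covering all 39.
#' @export
load_viseme_map <- function(path = system.file("extdata", "viseme_map.csv",
                                               package = "avsin")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("phoneme", "viseme") %in% names(tab)))
  map <- stats::setNames(tab$viseme, toupper(tab$phoneme))
  missing <- setdiff(ARPABET, names(map))
  if (length(missing) > 0L) {
    stop("viseme map does not cover: ", paste(missing, collapse = ", "))
  }
  map[ARPABET]
}

#' Default per-class, per-format phoneme transmission probabilities
#'
#' The generative model's core parameters: the probability that a stimulus
#' phoneme of a given viseme class survives into the perceived sequence under
#' each stimulus format. Defaults reflect the phoneme-level identification
#' rates characteristic of speech-in-noise at -12 dB SNR with real or
#' synthetic talking faces: auditory-only 0.37 for every class; real faces
#' 0.78; synthetic faces (DNN and FACS alike) 0.28 for the labiodental and
#' dental fricative classes — whose diagnostic teeth/lip/tongue features
#' synthetic renderers miss — and 0.61 for all other classes.
#'
#' @param viseme_map named phoneme-to-viseme vector from [load_viseme_map()].
#' @return Data frame with columns `viseme`, `format`, `prob` covering every
#'   viseme class x format combination.
#' @export
default_transmission <- function(viseme_map = load_viseme_map()) {
  classes <- sort(unique(viseme_map))
  degraded <- c("labiodental", "dental")
  grid <- expand.grid(viseme = classes,
                      format = c("An", "AnV_Real", "AnV_FACS", "AnV_DNN"),
                      stringsAsFactors = FALSE)
  grid$prob <- ifelse(grid$format == "An", 0.37,
               ifelse(grid$format == "AnV_Real", 0.78,
               ifelse(grid$viseme %in% degraded, 0.28, 0.61)))
  grid
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic experiment. Defaults emulate the
#' reference design: 61 participants, 64 noisy words (half per talker) each
#' seen once per participant in one of four counterbalanced formats, plus 9
#' clear audiovisual catch trials per participant with near-perfect
#' transmission.
#'
#' @param n_participants number of simulated participants.
#' @param n_words number of noisy stimulus words (must be divisible by the
#'   number of formats).
#' @param formats ordered format labels cycled across participants.
#' @param transmission data frame `viseme`, `format`, `prob` (defaults to
#'   [default_transmission()]).
#' @param slip_model what happens to an untransmitted phoneme: `"delete"`
#'   (dropped from the perceived sequence) or
#'   `"substitute_within_auditory_set"` (replaced by an acoustically
#'   confusable phoneme, e.g. its voicing partner).
#' @param lexical_reconstruction if TRUE (default), the simulated participant
#'   reports the lexicon word closest in Jaccard overlap to the perceived
#'   sequence — mimicking typed whole-word responses; if FALSE the perceived
#'   sequence itself is emitted (the identifiable mode used for parameter
#'   recovery).
#' @param catch_trials_per_participant clear catch trials per participant.
#' @param catch_transmission per-phoneme transmission on catch trials.
#' @param n_batches participants are assigned to this many recruitment
#'   batches round-robin.
#' @param seed integer seed governing every random choice.
#' @return List of class `avsin_sim_config`.
#' @export
sim_config <- function(n_participants = 61L,
                       n_words = 64L,
                       formats = c("AnV_Real", "AnV_FACS", "AnV_DNN", "An"),
                       transmission = default_transmission(),
                       slip_model = c("delete", "substitute_within_auditory_set"),
                       lexical_reconstruction = TRUE,
                       catch_trials_per_participant = 9L,
                       catch_transmission = 0.98,
                       n_batches = 4L,
                       seed = 1L) {
  slip_model <- match.arg(slip_model)
  if (n_words %% length(formats) != 0L) {
    stop("n_words must be divisible by the number of formats")
  }
  stopifnot(all(transmission$prob >= 0 & transmission$prob <= 1),
            catch_transmission >= 0, catch_transmission <= 1)
  structure(list(n_participants = as.integer(n_participants),
                 n_words = as.integer(n_words), formats = formats,
                 transmission = transmission, slip_model = slip_model,
                 lexical_reconstruction = lexical_reconstruction,
                 catch_trials_per_participant = as.integer(catch_trials_per_participant),
                 catch_transmission = catch_transmission,
                 n_batches = as.integer(n_batches), seed = as.integer(seed)),
            class = "avsin_sim_config")
}

transmission_lookup <- function(transmission) {
  stats::setNames(transmission$prob,
                  paste(transmission$viseme, transmission$format, sep = "\r"))
}

# acoustically confusable substitution sets: voicing pairs for obstruents,
# manner groups for sonorants, coarse height/backness groups for vowels
AUDITORY_SETS <- list(
  c("P", "B"), c("T", "D"), c("K", "G"), c("F", "V"), c("TH", "DH"),
  c("S", "Z"), c("SH", "ZH"), c("CH", "JH"), c("M", "N", "NG"),
  c("L", "R"), c("W", "Y"), c("HH"),
  c("IY", "IH", "EH", "EY", "AE"),
  c("UW", "UH", "OW", "AO", "OY"),
  c("AA", "AH", "ER", "AW", "AY")
)

substitute_phoneme <- function(ph) {
  set <- AUDITORY_SETS[[which(vapply(AUDITORY_SETS, function(s) ph %in% s,
                                     logical(1)))]]
  others <- setdiff(set, ph)
  if (length(others) == 0L) return(character(0))  # singleton set: deletion
  sample(others, 1L)
}

#' Draw the main and catch stimulus word sets
#'
#' Samples `n_words` unique noisy words (talker labels alternating female /
#' male) plus disjoint catch words from the eligible lexicon entries (>= 2
#' phonemes). Like a deliberately constructed stimulus set, the sample is
#' built to cover the phoneme inventory: every phoneme the lexicon can supply
#' appears in at least one main word (phonemes are seeded rarest-first, then
#' the remaining slots are filled at random), which also guarantees coverage
#' of every coverable viseme class. An error names any viseme class the
#' lexicon cannot cover at all.
#'
#' @param config `avsin_sim_config`.
#' @param lexicon an `avsin_lexicon`.
#' @param viseme_map phoneme-to-viseme vector.
#' @return List with `words` (data frame: word, talker), `catch_words`
#'   (data frame: word, face_type), `phonemizations` (named list, first
#'   lexicon variant per word).
#' @export
make_stimulus_set <- function(config, lexicon, viseme_map = load_viseme_map()) {
  eligible <- names(lexicon$entries)[
    vapply(lexicon$entries, function(v) length(v[[1]]) >= 2L, logical(1))]
  eligible <- sort(eligible)
  n_catch <- config$catch_trials_per_participant
  if (length(eligible) < config$n_words + n_catch) {
    stop("lexicon has only ", length(eligible), " eligible words; need ",
         config$n_words + n_catch)
  }
  word_ph <- lapply(eligible, function(w) unique(lexicon$entries[[w]][[1]]))
  names(word_ph) <- eligible
  coverable_ph <- sort(unique(unlist(word_ph)))
  coverable <- sort(unique(unname(viseme_map[coverable_ph])))
  all_classes <- sort(unique(viseme_map))
  uncoverable <- setdiff(all_classes, coverable)
  if (length(uncoverable) > 0L) {
    stop("lexicon cannot cover viseme class(es): ",
         paste(uncoverable, collapse = ", "))
  }

  # seed the sample with one word per coverable phoneme, rarest phonemes
  # first, then fill the remaining slots at random
  n_words_with <- vapply(coverable_ph, function(p)
    sum(vapply(word_ph, function(x) p %in% x, logical(1))), integer(1))
  main <- character(0)
  for (p in coverable_ph[order(n_words_with)]) {
    if (length(main) >= config$n_words) break
    if (any(vapply(word_ph[main], function(x) p %in% x, logical(1)))) next
    cands <- eligible[vapply(word_ph, function(x) p %in% x, logical(1))]
    cands <- setdiff(cands, main)
    main <- c(main, if (length(cands) > 1L) sample(cands, 1L) else cands)
  }
  remaining <- setdiff(eligible, main)
  main <- c(main, sample(remaining, config$n_words - length(main)))
  main <- sample(main)  # shuffle so talker labels are not phoneme-ordered
  catch <- sample(setdiff(eligible, main), n_catch)

  words <- data.frame(word = main,
                      talker = rep_len(c("female", "male"), length(main)))
  catch_words <- data.frame(word = catch,
                            face_type = rep_len(c("Real", "FACS", "DNN"),
                                                n_catch))
  phon <- lapply(lexicon$entries[c(main, catch)], `[[`, 1L)
  list(words = words, catch_words = catch_words, phonemizations = phon)
}

#' Counterbalanced format assignment
#'
#' Participant `i`, word `j` receives `formats[(i + j) mod k]`: every
#' participant sees each format on exactly `|words| / k` words, and across any
#' `k` consecutive participants every word appears in every format.
#'
#' @param n_participants number of participants.
#' @param words character vector of stimulus words.
#' @param formats ordered format labels.
#' @return `n_participants` x `length(words)` character matrix of formats,
#'   rows = participants.
#' @export
assign_formats <- function(n_participants, words,
                           formats = c("AnV_Real", "AnV_FACS", "AnV_DNN", "An")) {
  k <- length(formats)
  if (length(words) %% k != 0L) {
    stop("number of words must be divisible by the number of formats")
  }
  m <- outer(seq_len(n_participants), seq_along(words),
             function(i, j) formats[((i + j) %% k) + 1L])
  dimnames(m) <- list(NULL, words)
  m
}

# perceived phoneme sequence for one trial
perceive <- function(stim_ph, probs, slip_model) {
  kept <- stats::runif(length(stim_ph)) < probs
  if (slip_model == "delete") {
    stim_ph[kept]
  } else {
    out <- lapply(seq_along(stim_ph), function(i) {
      if (kept[i]) stim_ph[i] else substitute_phoneme(stim_ph[i])
    })
    unlist(out)
  }
}

# nearest lexicon word by Jaccard to a perceived sequence; ties alphabetical
make_reconstructor <- function(lexicon) {
  words <- rep(names(lexicon$entries), lengths(lexicon$entries))
  vars <- unlist(lexicon$entries, recursive = FALSE, use.names = FALSE)
  ord <- order(words)
  words <- words[ord]
  vars <- vars[ord]
  V <- t(vapply(vars, phoneme_counts, integer(length(ARPABET))))
  vlen <- lengths(vars)
  function(perceived) {
    pc <- phoneme_counts(perceived)
    n_int <- rowSums(pmin(V, rep(pc, each = nrow(V))))
    jac <- n_int / (vlen + length(perceived) - n_int)
    words[which.max(jac)]  # first index = alphabetically first on ties
  }
}

# lexicon token that phonemizes exactly to a given sequence (used when
# lexical reconstruction is off): apostrophe-separated so that response
# normalization preserves it as one token
sequence_token <- function(symbols) {
  paste0("x'", paste(tolower(symbols), collapse = "'"))
}

#' Simulate one typed response
#'
#' Each stimulus phoneme is transmitted independently with the probability
#' set by its viseme class and the trial format; untransmitted phonemes are
#' deleted or substituted according to the slip model. With lexical
#' reconstruction the response is the lexicon word with maximal Jaccard
#' overlap to the perceived sequence (alphabetical tie-break); without it the
#' perceived sequence itself is emitted as a generated lexicon token. An empty
#' perceived sequence falls back to a uniformly drawn lexicon word and is
#' flagged.
#'
#' @param word_phonemes stimulus phoneme sequence.
#' @param format trial format (`AV_catch` uses the catch transmission).
#' @param config `avsin_sim_config`.
#' @param viseme_map phoneme-to-viseme vector.
#' @param lexicon an `avsin_lexicon`.
#' @param reconstructor optional precomputed closure from
#'   `make_reconstructor()` (built on the fly if omitted).
#' @return List: `response` (text), `perceived` (phoneme vector),
#'   `empty_fallback` (logical).
#' @export
simulate_response <- function(word_phonemes, format, config,
                              viseme_map = load_viseme_map(),
                              lexicon, reconstructor = NULL) {
  if (format == "AV_catch") {
    probs <- rep(config$catch_transmission, length(word_phonemes))
  } else {
    lut <- transmission_lookup(config$transmission)
    key <- paste(viseme_map[word_phonemes], format, sep = "\r")
    probs <- unname(lut[key])
    if (anyNA(probs)) {
      stop("no transmission entry for: ",
           paste(unique(key[is.na(probs)]), collapse = "; "))
    }
  }
  perceived <- perceive(word_phonemes, probs, config$slip_model)
  if (length(perceived) == 0L) {
    return(list(response = sample(names(lexicon$entries), 1L),
                perceived = character(0), empty_fallback = TRUE))
  }
  if (config$lexical_reconstruction) {
    if (is.null(reconstructor)) reconstructor <- make_reconstructor(lexicon)
    resp <- reconstructor(perceived)
  } else {
    resp <- sequence_token(perceived)
  }
  list(response = resp, perceived = perceived, empty_fallback = FALSE)
}

#' Simulate a complete counterbalanced experiment
#'
#' Draws the stimulus set, assigns counterbalanced formats, simulates every
#' trial response under the viseme-transmission model, and shuffles trial
#' order within participant. All randomness derives from `config$seed`, so
#' identical configurations reproduce identical trial tables.
#'
#' @param config `avsin_sim_config`.
#' @param lexicon an `avsin_lexicon`.
#' @param viseme_map phoneme-to-viseme vector.
#' @return List with `trials` (data frame: participant, batch, word, format,
#'   face_type_for_catch, response), `lexicon` (the input lexicon, augmented
#'   with generated tokens when reconstruction is off — use this one for
#'   scoring), and `manifest` (generating parameters, stimulus set, counts of
#'   empty-sequence fallbacks).
#' @export
simulate_experiment <- function(config, lexicon, viseme_map = load_viseme_map()) {
  set.seed(config$seed)
  stim <- make_stimulus_set(config, lexicon, viseme_map)
  fmt <- assign_formats(config$n_participants, stim$words$word, config$formats)
  recon <- if (config$lexical_reconstruction) make_reconstructor(lexicon) else NULL

  rows <- vector("list", config$n_participants)
  n_fallback <- 0L
  new_entries <- list()
  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("P%03d", i)
    batch <- sprintf("B%d", ((i - 1L) %% config$n_batches) + 1L)
    n_main <- nrow(stim$words)
    n_catch <- nrow(stim$catch_words)
    word <- c(stim$words$word, stim$catch_words$word)
    format <- c(fmt[i, ], rep("AV_catch", n_catch))
    face_catch <- c(rep("none", n_main), stim$catch_words$face_type)
    response <- character(n_main + n_catch)
    for (j in seq_along(word)) {
      r <- simulate_response(stim$phonemizations[[word[j]]], format[j], config,
                             viseme_map, lexicon, recon)
      response[j] <- r$response
      if (r$empty_fallback) n_fallback <- n_fallback + 1L
      if (!config$lexical_reconstruction && !r$empty_fallback) {
        new_entries[[r$response]] <- r$perceived
      }
    }
    ord <- sample(length(word))
    rows[[i]] <- data.frame(participant = pid, batch = batch,
                            word = word[ord], format = format[ord],
                            face_type_for_catch = face_catch[ord],
                            response = response[ord])
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL

  score_lexicon <- lexicon
  if (length(new_entries) > 0L) {
    score_lexicon$entries <- c(score_lexicon$entries,
                               lapply(new_entries, list))
  }
  manifest <- list(config = unclass(config),
                   words = stim$words, catch_words = stim$catch_words,
                   n_empty_fallback = n_fallback,
                   n_trials = nrow(trials))
  list(trials = trials, lexicon = score_lexicon, manifest = manifest)
}
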