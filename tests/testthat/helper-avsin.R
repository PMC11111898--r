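# shared fixtures, built once per test run

lex_path <- system.file("extdata", "mini_cmudict.txt", package = "avsin")
LEX <- load_lexicon(lex_path)
EQUIV <- load_equivalences(system.file("extdata", "equivalences.csv",
                                       package = "avsin"))
VMAP <- load_viseme_map()
PREV <- load_prevalence(system.file("extdata",
                                    "phoneme_prevalence_synthetic.csv",
                                    package = "avsin"))

# independent multiset-Jaccard oracle: explicit per-symbol min-count loop,
# no shared code with jaccard_overlap()
brute_jaccard <- function(a, b) {
  n_int <- 0L
  for (sym in unique(c(a, b))) {
    n_int <- n_int + min(sum(a == sym), sum(b == sym))
  }
  n_union <- length(a) + length(b) - n_int
  list(jaccard = n_int / n_union, n_intersection = n_int, n_union = n_union)
}

random_sequence <- function(max_len = 8L, alphabet = ARPABET) {
  sample(alphabet, sample(1:max_len, 1L), replace = TRUE)
}

# small counterbalanced experiment for fast module tests
small_sim <- function(seed, n_participants = 8L, n_words = 16L,
                      catch = 3L, ...) {
  cfg <- sim_config(n_participants = n_participants, n_words = n_words,
                    catch_trials_per_participant = catch, seed = seed, ...)
  simulate_experiment(cfg, LEX)
}

# transmission table with a single probability everywhere (null generator)
flat_transmission <- function(p) {
  tr <- default_transmission(VMAP)
  tr$prob <- p
  tr
}

# transmission with the dental/labiodental classes degraded under synthetic
degraded_transmission <- function(p_degraded = 0.05) {
  tr <- default_transmission(VMAP)
  sel <- tr$viseme %in% c("dental", "labiodental") &
    tr$format %in% c("AnV_FACS", "AnV_DNN")
  tr$prob[sel] <- p_degraded
  tr
}

# hand-built scored-trial fixture covering the worked scoring examples
fixture_trials <- function() {
  data.frame(
    participant = rep(c("P1", "P2"), each = 4L),
    batch = "B1",
    word = c("polish", "ethic", "wore", "booth",
             "wormhole", "echos", "polish", "ethic"),
    format = c("An", "An", "AnV_Real", "AnV_Real",
               "AnV_FACS", "AnV_DNN", "AnV_Real", "AnV_FACS"),
    face_type_for_catch = "none",
    response = c("policy", "essay", "war", "boot",
                 "wormhole", "echoes", "polish", "ethic"))
}
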