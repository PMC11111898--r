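test_that("stimulus sets are deterministic, balanced across talkers, and cover visemes", {
  cfg <- sim_config(seed = 5)
  set.seed(cfg$seed)
  s1 <- make_stimulus_set(cfg, LEX, VMAP)
  set.seed(cfg$seed)
  s2 <- make_stimulus_set(cfg, LEX, VMAP)
  expect_identical(s1, s2)

  expect_equal(nrow(s1$words), 64L)
  expect_equal(as.integer(table(s1$words$talker)), c(32L, 32L))
  expect_length(intersect(s1$words$word, s1$catch_words$word), 0L)

  covered <- unique(unname(VMAP[unlist(s1$phonemizations[s1$words$word])]))
  expect_setequal(covered, unique(unname(VMAP)))

  # a lexicon with no bilabials cannot support the viseme model
  tiny <- LEX
  has_bilabial <- vapply(tiny$entries, function(v)
    any(c("P", "B", "M") %in% v[[1]]), logical(1))
  tiny$entries <- tiny$entries[!has_bilabial]
  cfg_small <- sim_config(n_words = 16L, catch_trials_per_participant = 3L)
  expect_error(make_stimulus_set(cfg_small, tiny, VMAP), "bilabial")
})

test_that("format assignment is a cycled Latin-square design", {
  formats <- c("AnV_Real", "AnV_FACS", "AnV_DNN", "An")
  m4 <- assign_formats(4, paste0("w", 1:4), formats)
  # 4 x 4 core: every word x format pair appears exactly once
  for (j in 1:4) expect_setequal(m4[, j], formats)
  for (i in 1:4) expect_setequal(m4[i, ], formats)

  m <- assign_formats(61, paste0("w", 1:64), formats)
  # every participant sees 16 words per format
  for (i in c(1, 30, 61)) {
    expect_equal(as.integer(table(m[i, ])), rep(16L, 4L))
  }
  # across participants, per-word format counts differ by at most one
  counts <- apply(m, 2, function(col) table(factor(col, levels = formats)))
  expect_lte(max(counts) - min(counts), 1L)
  expect_error(assign_formats(5, paste0("w", 1:10), formats), "divisible")
})

test_that("simulated experiments are reproducible and correctly sized", {
  cfg <- sim_config(n_participants = 6, seed = 99)
  sim1 <- simulate_experiment(cfg, LEX)
  sim2 <- simulate_experiment(cfg, LEX)
  expect_identical(sim1$trials, sim2$trials)

  expect_equal(nrow(sim1$trials), 6L * 73L)
  per <- table(sim1$trials$participant)
  expect_true(all(per == 73L))
  one <- sim1$trials[sim1$trials$participant == "P001", ]
  expect_equal(sum(one$format == "AV_catch"), 9L)
  expect_equal(as.integer(table(one$format[one$format != "AV_catch"])),
               rep(16L, 4L))
  # catch trials carry a face type, noisy trials do not
  expect_true(all((one$face_type_for_catch != "none") ==
                  (one$format == "AV_catch")))
})

test_that("the noiseless limit gives fully correct responses", {
  sim <- small_sim(seed = 3, n_participants = 4,
                   transmission = flat_transmission(1),
                   catch_transmission = 1)
  scored <- score_trials(sim$trials, sim$lexicon, EQUIV)
  # reconstruction can land on a homophone, which still scores correct
  expect_true(all(scored$word_correct))
  expect_true(all(scored$jaccard == 1))
})

test_that("the total-loss limit floors accuracy and flags empty percepts", {
  sim <- small_sim(seed = 4, n_participants = 4,
                   transmission = flat_transmission(0),
                   catch_transmission = 1,
                   lexical_reconstruction = FALSE)
  # with deletion slips and zero transmission every percept is empty
  expect_equal(sim$manifest$n_empty_fallback, 4L * 16L)

  # substitution slips leave a percept but share no phonemes worth much credit
  sim2 <- small_sim(seed = 4, n_participants = 4,
                    transmission = flat_transmission(0),
                    catch_transmission = 1,
                    slip_model = "substitute_within_auditory_set",
                    lexical_reconstruction = FALSE)
  scored <- score_trials(sim2$trials, sim2$lexicon, EQUIV)
  noisy <- scored[scored$format != "AV_catch", ]
  expect_true(all(!noisy$word_correct))
  expect_lt(mean(noisy$jaccard), 0.15)
})

test_that("with reconstruction off, per-phoneme rates estimate transmission", {
  # identifiable mode: the response is exactly the perceived sequence
  theta <- 0.6
  sim <- small_sim(seed = 8, n_participants = 10,
                   transmission = flat_transmission(theta),
                   lexical_reconstruction = FALSE)
  scored <- score_trials(sim$trials, sim$lexicon, EQUIV)
  rates <- count_identifications(scored)
  pooled <- sum(rates$n_identified) / sum(rates$n_presented)
  ci <- stats::binom.test(sum(rates$n_identified),
                          sum(rates$n_presented))$conf.int
  expect_true(theta >= ci[1] && theta <= ci[2])
  expect_lt(abs(pooled - theta), 0.05)
})

test_that("word accuracy rises monotonically with transmission probability", {
  acc <- vapply(c(0.2, 0.5, 0.8), function(p) {
    sim <- small_sim(seed = 12, transmission = flat_transmission(p))
    scored <- score_trials(sim$trials, sim$lexicon, EQUIV)
    mean(scored$word_correct[scored$format != "AV_catch"])
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})

test_that("typed-response reconstruction preserves the planted deficit qualitatively", {
  # realistic mode: lexical reconstruction on, default transmission (synthetic
  # dental/labiodental classes degraded)
  cfg <- sim_config(n_participants = 30, seed = 612)
  sim <- simulate_experiment(cfg, LEX)
  scored <- score_trials(sim$trials, sim$lexicon, EQUIV)
  s <- summarize_conditions(scored)$grand
  acc <- function(f) s$word_accuracy[s$format == f]
  expect_gt(acc("AnV_Real"), mean(c(acc("AnV_FACS"), acc("AnV_DNN"))))
  expect_gt(acc("AnV_FACS"), acc("An"))
  expect_gt(acc("AV_catch"), 0.95)

  rs <- real_synthetic_differences(count_identifications(scored))
  ranks <- match(c("TH", "DH", "F", "V"), rs$phoneme)
  expect_true(all(ranks <= 10))
  expect_gt(mean(rs$difference[ranks]), mean(rs$difference[-ranks]))
})
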