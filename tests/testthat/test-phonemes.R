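test_that("identification counts follow the min-multiplicity rule", {
  tr <- fixture_trials()
  scored <- score_trials(tr, LEX, EQUIV)
  rates <- count_identifications(scored)

  # ethic vs essay (P1, An): intersection is {EH} only
  p1 <- rates[rates$participant == "P1" & rates$face_type == "An", ]
  cell <- function(tab, ph) tab[tab$phoneme == ph,
                                c("n_identified", "n_presented")]
  expect_equal(unlist(cell(p1, "EH"), use.names = FALSE), c(1L, 1L))
  expect_equal(unlist(cell(p1, "TH"), use.names = FALSE), c(0L, 1L))
  expect_equal(unlist(cell(p1, "IH"), use.names = FALSE), c(0L, 2L))  # polish + ethic
  expect_equal(unlist(cell(p1, "K"), use.names = FALSE), c(0L, 1L))

  # perfect responses: every phoneme fully identified (P2 Real: polish/polish)
  p2r <- rates[rates$participant == "P2" & rates$face_type == "Real", ]
  expect_true(all(p2r$n_identified == p2r$n_presented))
})

test_that("presented counts conserve stimulus lengths and match a recount oracle", {
  sim <- small_sim(seed = 13)
  scored <- score_trials(sim$trials, sim$lexicon, EQUIV)
  rates <- count_identifications(scored)
  phon <- attr(scored, "phonemes")
  main <- scored$format != "AV_catch"

  expect_equal(sum(rates$n_presented),
               sum(lengths(lapply(phon[main], `[[`, "stimulus"))))

  # independent recount for one participant x face cell, trial by trial
  face <- c(An = "An", AnV_Real = "Real", AnV_FACS = "FACS", AnV_DNN = "DNN")
  idx <- which(scored$participant == "P003" & scored$format == "AnV_FACS")
  recount <- new.env()
  for (i in idx) {
    st <- phon[[i]]$stimulus
    rs <- phon[[i]]$response
    for (ph in unique(st)) {
      got <- min(sum(st == ph), sum(rs == ph))
      key <- ph
      prev <- if (is.null(recount[[key]])) c(0L, 0L) else recount[[key]]
      recount[[key]] <- prev + c(got, sum(st == ph))
    }
  }
  cell <- rates[rates$participant == "P003" & rates$face_type == "FACS", ]
  for (ph in ls(recount)) {
    row <- cell[cell$phoneme == ph, ]
    expect_equal(c(row$n_identified, row$n_presented), recount[[ph]])
  }
  expect_equal(nrow(cell), length(ls(recount)))
})

test_that("difference tables subtract in the documented direction and sort", {
  sim <- small_sim(seed = 17, n_participants = 12)
  scored <- score_trials(sim$trials, sim$lexicon, EQUIV)
  rates <- count_identifications(scored)

  rs <- real_synthetic_differences(rates)
  expect_equal(rs$difference, rs$real_rate - rs$synthetic_rate)
  expect_false(is.unsorted(rev(rs$difference)))
  expect_true(all(rs$adjusted_p >= rs$p - 1e-12))
  expect_true(all(rs$adjusted_p <= 1))

  # synthetic rate is the average of the DNN and FACS pooled rates
  ph <- rs$phoneme[1]
  pool <- function(f) {
    sub <- rates[rates$phoneme == ph & rates$face_type == f, ]
    sum(sub$n_identified) / sum(sub$n_presented)
  }
  expect_equal(rs$synthetic_rate[1], mean(c(pool("DNN"), pool("FACS"))))

  df <- dnn_vs_facs(rates)
  expect_equal(df$difference, df$dnn_rate - df$facs_rate)

  # a phoneme with identical sample rates has difference exactly 0
  fake <- data.frame(phoneme = "B", face_type = c("Real", "DNN", "FACS"),
                     participant = "P1", n_identified = c(5L, 5L, 5L),
                     n_presented = c(10L, 10L, 10L))
  fake$rate <- fake$n_identified / fake$n_presented
  rs0 <- real_synthetic_differences(fake)
  expect_equal(rs0$difference, 0)
  expect_false(rs0$significant)
})

test_that("glmm aggregation agrees with pooling on direction for strong effects", {
  sim <- small_sim(seed = 29, n_participants = 10,
                   transmission = degraded_transmission(0.05),
                   lexical_reconstruction = FALSE)
  scored <- score_trials(sim$trials, sim$lexicon, EQUIV)
  rates <- count_identifications(scored)
  pooled <- real_synthetic_differences(rates, method = "pooled")
  glmm <- real_synthetic_differences(rates, method = "glmm")
  top <- c("TH", "DH", "F", "V")
  expect_true(all(pooled$difference[pooled$phoneme %in% top] > 0))
  expect_true(all(glmm$difference[glmm$phoneme %in% top] > 0))
})

test_that("group contrast pairs participants and flags planted deficits", {
  # degraded dental/labiodental transmission under synthetic formats only,
  # in the identifiable (no-reconstruction) mode
  sim <- small_sim(seed = 41, n_participants = 12, n_words = 64,
                   transmission = degraded_transmission(0.05),
                   lexical_reconstruction = FALSE)
  scored <- score_trials(sim$trials, sim$lexicon, EQUIV)
  rates <- count_identifications(scored)
  gc <- group_contrast(rates)

  expect_equal(gc$condition, c("Real", "Synthetic", "Difference"))
  synth <- gc[gc$condition == "Synthetic", ]
  expect_lt(synth$t, 0)
  expect_lt(synth$p, 0.01)
  expect_lt(synth$group_mean, synth$rest_mean)
  expect_equal(synth$df, synth$n - 1)

  # degenerate input: fewer than three participants
  expect_error(group_contrast(rates[rates$participant %in% c("P001", "P002"), ]),
               ">= 3 participants")
})
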