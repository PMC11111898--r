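---
title: "Phoneme-level analysis of audiovisual speech-in-noise: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phoneme-level analysis of audiovisual speech-in-noise: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avsin)
```

## The problem

Seeing the face of a talker makes noisy speech dramatically easier to
understand, and synthetic talking faces — generated from audio by deep neural
networks (DNN) or driven by facial-action-coding-system (FACS) animation —
recover part but not all of that benefit. Word-identification experiments
that compare these face types produce a trial table: a participant heard a
noisy word in one of several formats (audio-only `An`; audiovisual with a
real face `AnV_Real`, a FACS face `AnV_FACS`, or a DNN face `AnV_DNN`; plus
clear `AV_catch` trials for attention checking) and typed what they heard.
This package turns such tables into the full analysis chain: word- and
phoneme-level scoring, condition and phoneme decompositions, a
counterfactual model of what better synthetic rendering would buy, power
calculations, and a generative simulator that makes every stage testable
without human data.

## Scoring typed responses

**Word level.** A response is correct if it equals the stimulus after
normalization (lowercasing; dropping characters other than letters,
apostrophes, hyphens and spaces; hyphens treated as spaces), if it is a
homophone of the stimulus (identical stress-stripped pronunciation in the
lexicon, e.g. *wore*/*war*), or if the pair appears in a curated equivalence
table of accepted misspellings (e.g. *echos*/*echoes*). The equivalence
table is a frozen data file rather than a fuzzy rule so that scoring is
deterministic; an edit-distance rule would silently admit real confusions
such as *booth*/*boot*, which must remain incorrect.

**Phoneme level.** Responses earn partial credit through the multiset
Jaccard index of the ARPAbet phonemizations of stimulus and response:

$$J = \frac{|S \cap R|}{|S| + |R| - |S \cap R|},$$

where the intersection counts each symbol with multiplicity
$\sum_p \min(n_S(p), n_R(p))$. Multiset (rather than set) semantics matter
because repeated phonemes carry information: *polish* (P AA L IH SH) against
the response *policy* (P AA L AH S IY) shares 3 phonemes of a union of 8,
giving $J = 3/8$.

Pronunciations come from a CMU-dictionary-format lexicon; vowel stress
digits are stripped at load time, leaving the canonical 39-symbol inventory.
Several deliberate choices:

* **Variant maximization.** Words with several pronunciation variants are
  scored with the variant pair maximizing $J$. The maximum is unique, so the
  rule is deterministic, and it is lenient in the same direction as accepting
  misspellings and homophones.
* **Full-credit propagation.** A trial judged word-correct through the
  homophone or misspelling route receives $J = 1$. The alternative
  (recomputing $J$ from the literal letters) would punish a participant the
  word-level rule had already credited; we treat the word-level judgement as
  authoritative.
* **Out-of-vocabulary fallback.** Typed responses contain typos that no
  dictionary covers. Rather than fail, an unknown token is phonemized by a
  fixed letter/digraph-to-phoneme map, and the trial carries an `oov_flag`
  that the run log counts. The map is intentionally crude; its only job is
  to be reproducible. Analyses can exclude flagged trials if desired.
* **Multi-word responses.** All tokens are phonemized and concatenated in
  order (the cross-product over token variants, capped at 16 combinations).

## Condition-level inference

Per-participant condition means are computed first and then averaged without
weighting, so participants — not trials — are the unit of analysis. The main
effect of stimulus format is a likelihood-ratio test between mixed-effects
models with and without the format fixed effect, with random intercepts for
word, participant, and recruitment batch (binomial family for word accuracy,
Gaussian on the Jaccard fraction for phoneme accuracy — a bounded response
treated linearly, acceptable at these intermediate accuracies). Pairwise
format contrasts use Tukey-adjusted estimated marginal means. Random slopes
are not included: each participant sees each word once, so slope variance is
weakly identified at best. When the mixed fit degenerates (or for large
simulation studies), a documented fixed-effects fallback runs the same
likelihood-ratio test with `glm`/`lm`; the simulator draws trials
independently given the design, so the fixed fit is calibrated there, and
200-rep null simulations in the test suite confirm a type-I error within
[0.02, 0.08] at nominal 0.05.

Individual differences are summarized by the benefit correlation: each
participant's real-face benefit (real minus audio-only accuracy) against
their synthetic benefit (mean of FACS and DNN benefits, minus audio-only),
as a Pearson correlation across participants.

## Phoneme-level decomposition

For each trial, a stimulus phoneme counts as identified
$\min(n_S(p), n_R(p))$ times out of $n_S(p)$ presentations — the same
min-multiplicity rule as the Jaccard intersection, applied per phoneme.
Counts accumulate per participant × face type, giving per-phoneme
identification rates.

The real-vs-synthetic difference table subtracts the synthetic rate (the
average of the DNN and FACS rates, not a trial-weighted pool, so both
synthetic types contribute equally) from the real rate, for each phoneme.
Significance uses a two-proportion z-test on pooled counts with Bonferroni
correction across the 39-phoneme family. A per-phoneme binomial mixed model
with participant random intercepts is available (`method = "glmm"`) and
agrees with pooling in direction; pooling is the default because it is
exactly reproducible, has no convergence failure modes, and is fast enough
to run inside the suite's 200-rep null-calibration study, where 39 mixed
fits per replicate would not be.

The four-phoneme contrast asks whether the dental (/TH DH/) and labiodental
(/F V/) fricatives — whose diagnostic visual features (tongue between teeth,
teeth on lip) synthetic renderers typically miss — behave differently from
the rest: each participant contributes a group mean and a rest mean, and a
paired t-test compares them within the Real condition, the Synthetic
condition, and on the real−synthetic difference.

## The counterfactual phoneme-presence model

To estimate what better rendering of a few phonemes would buy, word
accuracy on audiovisual trials is modelled with logistic regression on
phoneme *presence*: one indicator per phoneme (1 if the phoneme occurs at
least once in the stimulus word), one coefficient per phoneme per face class
(real vs synthetic, DNN and FACS pooled after the DNN–FACS comparison shows
no difference), plus one intercept per face class. The intercepts are
needed for identifiability — presence indicators are collinear across a
finite word list. Phonemes unseen in either face class are dropped with a
message. If the maximum-likelihood fit shows separation (non-convergence or
coefficients beyond ±15 log-odds), the model refits with a small fixed ridge
penalty (`glmnet`, α = 0, λ = 0.001) and flags itself `stabilized`; a
constant outcome vector is handled as an explicit degenerate case with zero
slopes and an empirical-logit intercept.

A logistic $r^2$ is not uniquely defined, so model fit is reported as the
squared Pearson correlation between observed per-word, per-face-class
accuracy and the model's mean predicted probability for the same cells,
with McFadden's pseudo-$r^2$ alongside.

The counterfactual replaces the synthetic-face coefficient of each improved
phoneme with its real-face coefficient and re-predicts mean accuracy over
the synthetic trials. Substituting the empty set returns the baseline;
substituting every phoneme yields real-face predictions (at the synthetic
intercept) evaluated on the synthetic words — both limits are tested.

**Prevalence extrapolation.** The tested words' phoneme distribution is not
the language's. Weighting each phoneme's per-condition rate by its relative
frequency in English and renormalizing over the phonemes present in both
tables predicts what a large-corpus experiment would show, per condition,
and hence the predicted real−synthetic difference. The packaged prevalence
file is a synthetic placeholder (and is named accordingly): published
English phoneme-frequency tables are licensed data the user should supply.

## Power analysis

Paired-design power uses the noncentral t distribution exactly: with $n$
pairs and standardized difference $d$, the test statistic is noncentral t
with $n-1$ degrees of freedom and noncentrality $d\sqrt{n}$, and power is
the probability of exceeding the two-tailed critical value. `required_n`
searches increment-and-check from $n = 2$. Two-tailed testing is fixed, as
is conventional for this design; the suite cross-checks the analytic power
against a 100,000-replicate Monte-Carlo paired-t simulation to ±0.01. The
two designed calculations — $d = 1.68$ at α = 0.05 and the conservative
$d = 0.5$ at α = 0.0167 (0.05/3 for three comparisons), both at 90% power —
give $n = 6$ and $n = 57$.

## The generative simulator

`simulate_experiment()` builds a complete experiment so that every analysis
stage has a ground truth:

* **Stimulus set.** 64 unique noisy words (32 per talker label) drawn from
  the lexicon plus 9 disjoint clear catch words. Like a deliberately
  constructed stimulus list, the draw is seeded to cover the phoneme
  inventory: every phoneme the lexicon can supply appears in at least one
  word (rarest first), which also guarantees viseme-class coverage.
* **Counterbalancing.** Participant $i$, word $j$ receives
  `formats[(i + j) mod 4]`: 16 words per format per participant, and every
  word cycles through all four formats across participants.
* **Response model.** Each stimulus phoneme survives into the perceived
  sequence independently with a transmission probability set by its viseme
  class and the trial format. Untransmitted phonemes are deleted or, under
  the alternative slip model, replaced by an acoustically confusable phoneme
  (voicing partners for obstruents, manner/height groups otherwise — a
  simple documented grouping, not a fitted confusion matrix). With *lexical
  reconstruction* on (the default, mimicking typed whole-word responses) the
  simulated participant reports the lexicon word with maximal Jaccard
  overlap to the percept, ties broken alphabetically; with reconstruction
  off the percept itself is emitted as a generated lexicon token, making
  per-phoneme rates unbiased estimates of the transmission probabilities —
  the identifiable mode used for parameter-recovery tests. An empty percept
  falls back to a random word and is counted in the manifest.
* **Default transmission probabilities** are fixed once at values realistic
  for −12 dB speech-in-noise with these face types: 0.37 for every class in
  `An`, 0.78 in `AnV_Real`, and for the synthetic formats 0.28 on the
  dental and labiodental classes and 0.61 elsewhere; catch trials use 0.98.
  The degraded synthetic classes encode the phenomenon of interest — missing
  teeth/lip/tongue cues — as the generative ground truth.

What the simulator does *not* emulate is worth stating: there is no
participant- or word-level random variation beyond the transmission
process, no fatigue or learning, no acoustic confusion structure tied to
the actual noise spectrum, and the mini-lexicon (about 215 words) is far
denser in neighbours than real English vocabulary, so lexical
reconstruction recovers words more easily than human listeners do. Passing
recovery tests therefore validates the analysis machinery, not the human
numbers; with reconstruction on, whole-word guessing spills errors across
the phonemes of a word, which compresses and mixes per-phoneme rates
relative to the generating probabilities (visible as inflated synthetic
rates for the degraded classes). This is why rank-recovery tests run in the
reconstruction-off mode, while the reconstruction-on mode is checked for
the qualitative pattern (real > synthetic > audio-only; the four degraded
phonemes in the top ranks of the difference table; catch accuracy above
95%).

## Numerical and degenerate-input choices

* Jaccard requires non-empty sequences; empty text after normalization is an
  error (`"empty response"`).
* Phonemes absent from a face type are excluded from difference tables, and
  phonemes missing from the prevalence table are dropped with renormalization
  — both logged, never silent.
* Benefit correlations refuse zero-variance benefit vectors; group contrasts
  require at least three complete participants.
* All simulation randomness derives from a single integer seed;
  reruns are byte-identical.

## Problem sizes used in the shipped studies

The analysis drivers simulate the full design (61 participants × 73 trials).
The test suite uses the full design where the property concerns it
(counterbalancing, parameter recovery at n = 60) and smaller cohorts
(8–20 participants, 16 words) for unit-level properties; the null
calibration study runs 200 replicates of a 12-participant, 16-word design,
which is ample for a rejection-rate check at nominal 5%.
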