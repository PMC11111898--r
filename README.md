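# avsin — phoneme-level analysis of audiovisual speech-in-noise perception

Seeing a talker's face makes noisy speech easier to understand; synthetic
talking faces (DNN- or FACS-generated) recover only part of that benefit.
`avsin` analyses word-identification experiments that compare such face
types. It takes a trial table (participant, batch, stimulus word, format ∈
{`An`, `AnV_Real`, `AnV_FACS`, `AnV_DNN`, `AV_catch`}, typed response) and a
CMU-format pronouncing lexicon, and provides:

* **Scoring** — word-level correctness (exact match after normalization,
  homophones, curated misspellings) and phoneme-level partial credit via the
  multiset Jaccard index

  J = |S ∩ R| / (|S| + |R| − |S ∩ R|),

  where the intersection counts every ARPAbet symbol with multiplicity
  min(n_S(p), n_R(p)). Example: stimulus *polish* (P AA L IH SH) vs response
  *policy* (P AA L AH S IY) → J = 3/8.
* **Condition inference** — per-participant condition means, a mixed-effects
  main effect of format (random intercepts for word, participant, batch;
  likelihood-ratio test) with Tukey-adjusted pairwise contrasts, and
  cross-participant benefit correlations.
* **Phoneme decomposition** — per-phoneme identification rates by face type,
  the real-minus-synthetic difference table with Bonferroni correction
  across the 39-phoneme family, the paired contrast of the dental and
  labiodental fricatives /TH DH F V/ against all other phonemes, and the
  DNN-vs-FACS comparison.
* **Counterfactual modelling** — a logistic model of word accuracy on
  per-face-class phoneme-presence indicators; substituting real-face
  coefficients for the synthetic-face coefficients of chosen phonemes
  predicts the accuracy gain from rendering those phonemes realistically.
  A prevalence-weighted extrapolation predicts large-corpus accuracy.
* **Power analysis** — exact noncentral-t power and sample size for paired
  (two-dependent-means) designs.
* **Simulation** — a seeded generative model (counterbalanced design +
  per-viseme-class phoneme transmission + lexical reconstruction of typed
  responses) so every stage is testable without human data.

## Worked example

```r
library(avsin)

lex   <- load_lexicon(system.file("extdata", "mini_cmudict.txt", package = "avsin"))
equiv <- load_equivalences(system.file("extdata", "equivalences.csv", package = "avsin"))

# scoring rules on the classic cases
score_word("wore", "war", lex, equiv)        # TRUE  (homophone)
score_word("booth", "boot", lex, equiv)      # FALSE (real confusion)
score_trial("polish", "policy", lex, equiv)$jaccard   # 0.375
score_trial("ethic",  "essay",  lex, equiv)$jaccard   # 0.1667

# simulate and analyse a full experiment
sim    <- simulate_experiment(sim_config(seed = 20240509), lex)
report <- run_pipeline(sim$trials, sim$lexicon, equiv)
report
```

The numbered drivers under `analysis/` run the same chain step by step and
write tables under `results/`. On the default simulation they print:

```
  An        word  24.6%   phoneme  41.7%
  AnV_DNN   word  54.6%   phoneme  68.6%
  AnV_FACS  word  55.0%   phoneme  68.9%
  AnV_Real  word  78.3%   phoneme  86.5%
  AV_catch  word  98.7%   phoneme  99.4%

word accuracy: format main effect chi2_3 = 641.0, p = 1.33e-138 [mixed]
benefit correlation (real vs synthetic, word): r = 0.66, p = 9.9e-09, n = 61
benefit correlation (real vs synthetic, phoneme): r = 0.72, p = 6.24e-11, n = 61

/TH DH F V/ vs other phonemes (paired across participants):
   condition group_mean rest_mean      t df        p  n
1       Real      0.864     0.899  -1.27 60 2.10e-01 61
2  Synthetic      0.483     0.754 -10.14 60 1.27e-14 61

Logistic phoneme-presence model: 2928 trials, fit r2 = 0.86
Synthetic word accuracy: baseline 54.8% -> 57.6% after giving /TH DH F V/
real-face coefficients
```

Reading this: audiovisual formats beat audio-only and real faces beat both
synthetic types; catch-trial accuracy near ceiling confirms simulated task
engagement; the four fricatives whose visual cues synthetic faces miss are
markedly worse *only* under synthetic faces (48% vs 75%, not under real
faces); and the counterfactual says rendering just those four phonemes
realistically would raise synthetic-face word accuracy by about three
points on this lexicon.

The generator's transmission probabilities are fixed at values realistic
for −12 dB speech-in-noise (audio-only 0.37, real face 0.78, synthetic 0.61
with the dental/labiodental classes degraded to 0.28, catch 0.98); see the
methods vignette (`vignettes/avsin-methods.Rmd`) for the model, its
assumptions, and what the simulation does and does not emulate.

## Package layout

```
R/                 scoring, lexicon, cohort, phoneme, counterfactual,
                   power, simulation, pipeline modules
analysis/          numbered narrative drivers (simulate → ... → power)
inst/extdata/      mini CMU-format lexicon, viseme map, misspelling
                   equivalences, synthetic prevalence placeholder
tests/testthat/    unit, property and end-to-end acceptance tests
scripts/           acceptance.R
vignettes/         methods vignette
```
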