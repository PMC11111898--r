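#!/usr/bin/env Rscript
# Sample-size calculations for the paired (two-dependent-means) design:
# the pilot effect size and the conservative design calculation with a
# Bonferroni-corrected alpha for three comparisons.

suppressPackageStartupMessages(library(avsin))

pilot <- required_n(d = 1.68, alpha = 0.05, target_power = 0.90)
cat(sprintf("Pilot effect (d = 1.68, alpha = 0.05): n = %d (power %.3f)\n",
            pilot$n, pilot$achieved_power))

conservative <- required_n(d = 0.5, alpha = 0.05 / 3, target_power = 0.90)
cat(sprintf("Conservative design (d = 0.5, alpha = 0.05/3 = 0.0167): n = %d (power %.3f)\n",
            conservative$n, conservative$achieved_power))

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(list(pilot = pilot, conservative = conservative),
                     "results/power.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/power.json\n")
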