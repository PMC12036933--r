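#!/usr/bin/env Rscript
# Calibration and recovery at reduced scale (the test suite runs the full
# 2000-study calibration and 200-study recovery): type-I error of the group
# t-test under the null generator, and direction recovery under the declared
# study-direction effects.

library(somamorph)

rate <- simulate_null_calibration(n_studies = 500, seed = 99)
cat("null calibration over 500 studies: rejection rate", rate, "\n")

rec <- simulate_recovery(n_studies = 25, effects = study_effects(), seed = 99)
readr::write_tsv(rec, "results/recovery.tsv")
cat("direction recovery over 25 studies:\n")
print(colMeans(as.matrix(rec[, -1])))
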