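#!/usr/bin/env Rscript
# Generate the synthetic study emulating the experimental design: 6 statin-
# treated vs 7 control birds, HVC and NCM sectioned at 6 um every 8th section,
# counted new-neuron (BrdU+/Hu+) and DCX+ markers, and traced soma contours
# for the new and older HVC neuron populations under the study-direction
# effects (flatter, rougher new neurons; smaller older neurons; no density
# effect). Writes the study CSVs and ground truth under results/study/.

library(somamorph)

seed <- 20240901
study <- gen_study(n_statin = 6, n_control = 7, effects = study_effects(),
                   seed = seed)
print(study)

dir.create("results", showWarnings = FALSE)
write_study(study, "results/study")
cat("study written to results/study (seed", seed, ")\n")

# sanity: regenerating from the same seed is identical
stopifnot(identical(gen_study(6, 7, study_effects(), seed)$markers,
                    study$markers))
cat("regeneration check: identical\n")
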