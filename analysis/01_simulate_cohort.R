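#!/usr/bin/env Rscript
# Simulate the calibration cohort: 815 children, ~51% girls, ages 6-11,
# four BMI groups in the study's proportions, group-specific mass and CMJ
# distributions, three flight-time trials per child. Writes the cohort in
# the package's CSV schema for the downstream steps.

library(pepower)

seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(rng_seed = seed)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort.csv")

message(sprintf("simulated %d subjects (%.0f%% girls)", nrow(cohort),
                100 * mean(cohort$sex == "girl")))
print(table(cohort$bmi_group))
message("wrote results/cohort.csv")
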