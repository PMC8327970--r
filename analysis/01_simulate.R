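#!/usr/bin/env Rscript
# Step 1: generate the synthetic study datasets used by the rest of the
# workflow.
#
# Two datasets are written:
#   - clean:   36 candidate trait variables (2 sexes x 9 teeth x 2
#              metrics), no planted confounders, study-like sizes.
#   - planted: same roster with the study's confounder pattern planted —
#              directional asymmetry in the four mandibular M1/M2 length
#              variables and trait-size dependency in the male maxillary
#              P3 length — so the screening and elimination steps have a
#              known right answer.
# Replicate trials 9-10 of both datasets carry twice the measurement
# error SD, giving the ME scan (step 2) a planted signal as well.

library(flucasym)

seed <- 1L
out_dir <- "results"
data_dir <- "scratch"
dir.create(out_dir, showWarnings = FALSE)
dir.create(data_dir, showWarnings = FALSE)

me_by_trial <- c(rep(0.01, 8), rep(0.02, 2))  # mm, per-trial error SD

message("simulating clean study (36 variables, J = 40, M = 10) ...")
clean_cfgs <- study_configs(n_individuals = 40, n_replicates = 10,
                            sigma_me = me_by_trial)
clean <- simulate_study(clean_cfgs, seed = seed)
write_measurements(clean, file.path(data_dir, "synthetic_clean.csv"))

message("simulating planted-confounder study (J = 200, M = 10) ...")
da4 <- c("female.MNM1.length", "female.MNM2.length",
         "male.MNM1.length", "male.MNM2.length")
planted_cfgs <- study_configs(n_individuals = 200, n_replicates = 10,
                              sigma_me = me_by_trial,
                              da_traits = da4, da_offset = 0.3,
                              size_dep_traits = "male.MXP3.length",
                              size_dep_gamma = 8)
planted <- simulate_study(planted_cfgs, seed = seed + 1L)
write_measurements(planted, file.path(data_dir, "synthetic_planted.csv"))

message(sprintf("wrote %d clean and %d planted measurement records",
                nrow(clean), nrow(planted)))
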