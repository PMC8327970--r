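#!/usr/bin/env Rscript
# Step 2: measurement-error scan across replicate subsets.
#
# Rebuilds per-trait matrices for each contiguous replicate subset and
# summarizes ME3 (the percentage of nondirectional between-sides
# variance attributable to measurement error) across the 36 variables.
# Trials 9-10 of the synthetic data carry double error SD, so subsets
# containing them should show elevated ME3 — the same reasoning the
# study used to choose its replicate set.

library(flucasym)

rec <- read_measurements("scratch/synthetic_clean.csv")
subsets <- list(9:10, 5:6, 6:9, 2:5, 4:7, 3:8, 2:9, 1:10)
scan <- replicate_scan(rec, subsets)
write.table(scan, "results/me_scan.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

print(scan, digits = 3)
worst <- scan$subset_label[which.max(scan$mean)]
best <- scan$subset_label[which.min(scan$mean)]
message(sprintf("highest mean ME3 in subset %s, lowest in %s", worst, best))
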