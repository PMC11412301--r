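#!/usr/bin/env Rscript
# Stage 3: perceptual outcomes — constant error (accuracy) and variable
# error (precision) of torque matching, per participant and load.

library(torquematch)

features <- read.delim("results/features.tsv")
perc <- perception_outcomes(features)
write.table(perc, "results/perception.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message("Per-load perceptual outcomes (mean +/- SD across participants):")
for (ld in sort(unique(perc$load))) {
  ce <- perc$ce_nm[perc$load == ld]
  ve <- perc$ve_nm[perc$load == ld]
  message(sprintf("  %2.0f%% load: CE %+.2f+/-%.2f Nm, VE %.2f+/-%.2f Nm",
                  100 * ld, mean(ce), sd(ce), mean(ve), sd(ve)))
}
message("Written to results/perception.tsv")
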