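#!/usr/bin/env Rscript
# Stage 4: muscle synergy extraction.
#
# Per participant: assemble the 8 x 48 activity matrix (mean normalized EMG,
# two phases x eight trials x three loads), row-normalize, factor with NMF
# and select the minimal synergy count reaching 95% VAF. Then derive the
# random-synergy similarity threshold and match synergies across
# participants against a reference participant.

library(torquematch)

seed <- 20260929L
features <- read.delim("results/features.tsv")
pids <- unique(features$participant)

models <- list()
for (i in seq_along(pids)) {
  pf <- features[features$participant == pids[i], ]
  am <- normalize_matrix(assemble_matrix(pf))
  models[[pids[i]]] <- select_synergy_count(am, seed = seed + i)
}

counts <- vapply(models, `[[`, integer(1), "n")
vafs <- vapply(models, `[[`, numeric(1), "vaf")
message(sprintf("Synergy counts: %s",
                paste(names(table(counts)), table(counts),
                      sep = "x", collapse = ", ")))
message(sprintf("Selected-model VAF: %.1f +/- %.1f%%",
                100 * mean(vafs), 100 * sd(vafs)))

th <- random_synergy_threshold(dim = 8, n_random = 1000, seed = seed)
message(sprintf("Chance-similarity threshold (95th pct of 10^6 products): %.3f",
                as.numeric(th)))

group <- match_synergies(models, th, reference = pids[1])
shared <- vapply(group$matches, function(m) sum(!is.na(m)), integer(1))
message(sprintf("Synergies matched to the reference: %d of %d participants share all %d",
                sum(shared == models[[pids[1]]]$n), length(pids) - 1L,
                models[[pids[1]]]$n))

vaf_curves <- do.call(rbind, lapply(names(models), function(pid) {
  data.frame(participant = pid, n = seq_along(models[[pid]]$vaf_curve),
             vaf = models[[pid]]$vaf_curve)
}))
write.table(vaf_curves, "results/vaf_curves.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

mean_W <- data.frame(muscle = rownames(group$mean_W), group$mean_W)
write.table(mean_W, "results/group_mean_synergies.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
jsonlite::write_json(
  list(threshold = as.numeric(th), reference = group$reference_participant,
       synergy_counts = as.list(table(counts)),
       vaf_mean_pct = 100 * mean(vafs), vaf_sd_pct = 100 * sd(vafs),
       matches = group$matches),
  "results/group_synergy.json", auto_unbox = TRUE, digits = NA)
message("Written: results/vaf_curves.tsv, results/group_mean_synergies.tsv, results/group_synergy.json")
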