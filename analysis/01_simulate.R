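#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume, at study
# scale: a 3-vs-3 spectral-count comparison (1000 proteins, 20 planted
# 8-fold enrichments, 15 MF-exclusive), a 73-construct interaction screen in
# triplicate with 6 planted pairs (one homophilic) and 2 sticky preys, a
# two-bait-experiment pull-down table, and a BLI titration at K_D 1.4 uM.

library(synscreen)

seed <- 20260926L
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

message("-- spectral counts --")
counts <- gen_spectral_counts(count_sim_config(
  seed = seed, n_proteins = 1000, n_enriched = 20, enrichment_fold = 8,
  baseline_mean = 30, dispersion = 100, n_exclusive = 15))
write_spectral_counts(counts$counts, "results/sim/spectral_counts.tsv")
write.table(counts$truth, "results/sim/spectral_counts_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  %d proteins (%d enriched, %d exclusive planted)",
                nrow(counts$counts), 20, 15))

message("-- ELISA screen --")
screen <- gen_elisa_screen(screen_sim_config(
  seed = seed, n_constructs = 73, n_experiments = 3,
  true_pairs = list(c(1, 10), c(5, 40), c(12, 12), c(20, 61), c(33, 70),
                    c(44, 52)),
  n_sticky_preys = 2, detection_prob = 0.9))
write_screen_long(screen$experiments, "results/sim/screen_plates.tsv")
write.table(as.data.frame(screen$truth$true_pairs),
            "results/sim/screen_truth_pairs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
d <- screen_design(73)
message(sprintf("  %d wells/experiment, %d unique pairs, %d tagged constructs",
                d$wells_per_experiment, d$unique_pairs,
                d$total_tagged_constructs))
message(sprintf("  sticky preys planted: %s",
                paste(screen$truth$sticky_preys, collapse = ", ")))

message("-- ecto-Fc pull-down --")
pd <- gen_pulldown(seed = seed, n_proteins = 300, n_bait_experiments = 2,
                   hit_fraction = 0.05, contaminant_fraction = 0.25)
write_pulldown(pd$table, "results/sim/pulldown.tsv")
write.table(pd$truth, "results/sim/pulldown_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("  %d proteins (%d planted hits)", nrow(pd$table),
                sum(pd$truth$class == "hit")))

message("-- BLI titration --")
bli <- gen_bli_series(bli_sim_config(seed = seed, kd_true = 1.4,
                                     rmax_true = 1, noise_sd = 0.02))
write_bli_series(bli, "results/sim/bli_series.tsv")
message(sprintf("  %d concentrations, %.3f down to %.3f uM",
                length(bli$concentrations), max(bli$concentrations),
                min(bli$concentrations)))
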