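#!/usr/bin/env Rscript
# Ecto-Fc pull-down hit filtering on the simulated two-experiment table,
# in both modes: whole-brain (absent from Fc control, >= 2 counts per bait
# experiment) and MF-synaptosome (<= 1 control count, >= 2 per experiment).

library(synscreen)

pd <- read_pulldown("results/sim/pulldown.tsv")
truth <- read.delim("results/sim/pulldown_truth.tsv")

wb <- filter_whole_brain(pd)
mf <- filter_mf(pd)
write_pulldown(wb, "results/pulldown_hits_wholebrain.tsv")
write_pulldown(mf, "results/pulldown_hits_mf.tsv")

hits <- truth$protein_id[truth$class == "hit"]
message(sprintf("input: %d proteins, %d planted hits", nrow(pd), length(hits)))
message(sprintf("whole-brain filter: %d retained (%d planted hits, %d other)",
                nrow(wb), sum(wb$protein_id %in% hits),
                sum(!wb$protein_id %in% hits)))
message(sprintf("MF filter: %d retained (%d planted hits, %d other)",
                nrow(mf), sum(mf$protein_id %in% hits),
                sum(!mf$protein_id %in% hits)))
message(sprintf("containment check: whole-brain subset of MF filter = %s",
                all(wb$protein_id %in% mf$protein_id)))
message("top MF-filter hits by total bait counts:")
print(head(mf, 5))
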