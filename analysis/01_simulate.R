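#!/usr/bin/env Rscript

# Step 1 — simulate the study: a 10 Mb two-chromosome genome with 1000
# genes, four differentiation stages (E12 NPCs -> E13/E14/E16 neurons) x
# two replicates of DNase cut sites, H3K4me3/H3K27me3 ChIP tracks planting
# bivalent promoters, and an NB count matrix following planted expression
# trajectories. Everything downstream reads the fixture written here.

suppressMessages(library(dhsdyn))

out_dir <- "results/fixture"
cfg <- sim_config(seed = 1L)
bundle <- simulate_bundle(cfg)
manifest <- write_fixture_bundle(bundle, out_dir)

cat("Simulated", cfg$n_genes, "genes on", cfg$n_chroms, "x",
    format(cfg$chrom_length, big.mark = ","), "bp\n")
cat("Planted dynamic classes:\n")
print(table(bundle$truth$dynamic_class))
cat("Planted marks: bivalent =", sum(bundle$truth$bivalent),
    ", K4-only =", sum(bundle$truth$k4 & !bundle$truth$bivalent),
    ", K27-only =", sum(bundle$truth$k27 & !bundle$truth$bivalent), "\n")
cat("Wrote", nrow(manifest), "files to", out_dir, "\n")
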