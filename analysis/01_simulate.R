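#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — a 4 Mb two-chromosome genome with
# 300 gene models, 500 binding peaks (80% placed within 3 kb upstream of a
# TSS), planted G-box and DOF motif architecture, negative-binomial
# occupancy counts for two genotypes, and DEG tables with a planted shared
# and cooperative gene structure.  Everything downstream reads results/data.

suppressPackageStartupMessages(library(cobind))

seed <- as.integer(Sys.getenv("COBIND_SEED", "1"))
cfg <- sim_config(seed = seed)
ds <- simulate_dataset(cfg, outdir = "results/data")

cat("Simulated", length(ds$genome), "chromosomes,",
    nrow(ds$genes), "genes,", nrow(ds$peaks), "peaks\n")
cat("Planted:", length(ds$truth$affected_peak_ids),
    "peaks with reduced occupancy (log2fc", cfg$effect_log2fc, "),",
    length(ds$truth$shared_gene_ids), "shared DEGs,",
    length(ds$truth$cooperative_gene_ids), "cooperative genes\n")
cat("Outputs in results/data (FASTA, GFF3, BED, narrowPeak, TSV, truth.json)\n")
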