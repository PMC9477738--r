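#!/usr/bin/env Rscript
# Stage 2: assign peaks to genes (3 kb upstream / 1 kb downstream windows,
# every qualifying gene linked), profile peak positions on the metagene
# axis, and compare against 1,000 random length-matched peak sets.

suppressPackageStartupMessages(library(cobind))

seed <- as.integer(Sys.getenv("COBIND_SEED", "1"))
genome <- read_fasta("results/data/genome.fa")
genes <- read_genes("results/data/genes.gff3")
peaks <- read_peaks("results/data/peaks.bed", "bed6")

ac <- annotation_config()
links <- assign_peaks_to_genes(peaks, genes, ac)
write.table(links, "results/links.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

prof <- metagene_profile(peaks, genes, links, config = ac)
env <- random_peak_null(peaks, setNames(nchar(genome), names(genome)),
                        genes, ac, n_sets = 1000L, seed = seed)
write.table(data.frame(bin_lo = prof$bin_edges[-length(prof$bin_edges)],
                       bin_hi = prof$bin_edges[-1],
                       observed = prof$density, null_mean = env$mean,
                       null_lo95 = env$lo95, null_hi95 = env$hi95),
            "results/metagene_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

upstream <- unique(links$peak_id[links$category == "upstream"])
cat(nrow(links), "links for", length(unique(links$peak_id)), "of",
    nrow(peaks), "peaks;",
    round(100 * length(upstream) / nrow(peaks), 1),
    "% of peaks lie within 3 kb upstream of a TSS\n")
mid <- (prof$bin_edges[-1] + prof$bin_edges[-length(prof$bin_edges)]) / 2
up <- mid < 0
cat("Upstream bins above the null hi95:",
    sum(prof$density[up] > env$hi95[up]), "of", sum(up), "\n")
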