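#!/usr/bin/env Rscript
# Stage 3: scan peaks for the G-box (CACGTG) and the DOF core (AAAAG),
# tabulate per-peak counts, consecutive-motif spacing against the
# non-target promoter background, and central enrichment within peaks.

suppressPackageStartupMessages(library(cobind))

genome <- read_fasta("results/data/genome.fa")
genes <- read_genes("results/data/genes.gff3")
peaks <- read_peaks("results/data/peaks.bed", "bed6")
links <- read.delim("results/links.tsv")
targets <- unique(links$gene_id)

specs <- builtin_motifs()[c("gbox", "dof")]
hits <- lapply(specs, function(s) scan_peaks(genome, peaks, s))
write.table(do.call(rbind, hits), "results/motif_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (m in names(specs)) {
  counts <- motif_counts_per_peak(hits[[m]], peaks)
  freq <- count_frequency(counts)
  sp <- spacing_distances(hits[[m]])
  bg <- background_spacing(genes, targets, genome, specs[[m]])
  ce <- central_enrichment(hits[[m]], peaks, specs[[m]])
  write.table(freq, sprintf("results/%s_count_frequency.tsv", m),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "%s: %d hits; %.1f%% of peaks with >=1 site; spacing mode %s bp (background %s bp); best central window +/-%d bp (adj p %.2g)\n",
    m, nrow(hits[[m]]), 100 * mean(counts > 0), sp$mode_estimate,
    bg$mode_estimate, ce$halfwidth[ce$best], ce$p_adj[ce$best]))
}
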