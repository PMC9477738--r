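# cobind

Peak-architecture and co-regulation analysis for a pair of cooperating
transcription factors, built around the regulatory logic of a bHLH factor
(binding the palindromic G-box, CACGTG) that strengthens and re-targets the
DNA binding of a single zinc-finger DOF factor (core motif [T/A]AAAG). The
DOF core is so common in plant genomes that it cannot explain target choice
by itself; the analyses here quantify the evidence that partner binding
does: where peaks sit relative to genes, what motif architecture they
carry, whether binding strength tracks motif content, which peaks lose
occupancy when the partner is absent, and which genes are supported by
every evidence layer at once.

The package implements, as tested R functions:

* **I/O** — BED6/narrowPeak, GFF3 gene models, FASTA, count matrices and
  DEG tables, all normalized to 0-based half-open coordinates.
* **Peak annotation** — assignment of each peak to *every* gene whose
  span ±(3 kb upstream / 1 kb downstream, gene orientation) contains the
  peak anchor; metagene profiles; a null envelope from 1,000 random peak
  sets with the observed length multiset placed uniformly.
* **Motif architecture** — exact IUPAC consensus scanning on both strands
  (palindromes reported once), per-peak counts, consecutive-motif spacing
  (start-to-start) against a non-target promoter background, and binomial
  central-enrichment tests.
* **Occupancy statistics** — binding-strength stratification by motif
  count with a tie-corrected Kruskal-Wallis test, pairwise Wilcoxon
  rank-sum tests (BH-adjusted) and a compact letter display; per-peak
  differential occupancy from replicated counts (median-of-ratios
  normalization, empirical-Bayes moderated t, FDR ≤ 0.05).
* **Co-regulation** — DEG filtering at 1.5-fold / adjusted p < 0.05,
  hypergeometric overlap tests, direction-consistency classification, and
  the four-way evidence intersection defining the cooperative gene set.
* **Synthetic data** — a generator that plants positional enrichment,
  motif counts and spacings, occupancy effects and DEG structure with a
  complete ground-truth record, so every stage is testable against known
  answers. Planted peaks are rescanned until the scanner finds exactly
  the planted sites, making truth and scan provably identical.

## Statistical core

For group comparisons of binding strength the package computes the
tie-corrected Kruskal-Wallis statistic

H = [12 / (N(N+1)) · Σᵢ Rᵢ²/nᵢ − 3(N+1)] / [1 − Σ(t³−t)/(N³−N)]

against χ²(g−1), and all pairwise two-sided Wilcoxon rank-sum tests via
the tie-corrected normal approximation, BH-adjusted; letters are assigned
by insert-and-absorb so groups share a letter exactly when their adjusted
p ≥ α. Differential occupancy tests log2(normalized count + 0.5) with
per-peak variances shrunk toward a moment-matched scaled-inverse-χ² prior
(the moderated t that small-replicate designs require). Gene-set overlaps
use the hypergeometric upper tail P(X ≥ k).

## Worked example

The `analysis/` scripts run a complete simulated study end to end
(`COBIND_SEED` selects the seed, default 1):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_annotate.R
Rscript analysis/03_motifs.R
Rscript analysis/04_occupancy.R
Rscript analysis/05_coregulation.R
```

A seed-1 run prints, among other lines:

```
Simulated 2 chromosomes, 300 genes, 500 peaks
Planted: 50 peaks with reduced occupancy (log2fc -2.5), 30 shared DEGs, 10 cooperative genes
524 links for 427 of 500 peaks; 82.6 % of peaks lie within 3 kb upstream of a TSS
Upstream bins above the null hi95: 17 of 17
gbox: 212 hits; 29.4% of peaks with >=1 site; spacing mode 27.5 bp ...
dof: 1104 hits; 94.8% of peaks with >=1 site; spacing mode 17.5 bp (background 7.5 bp) ...
Binding strength vs G-box count: Kruskal-Wallis H = 263.31 , p = 8.63e-57
Letters: 0=a  1=b  2=c  >=3=d
53 of 500 peaks differentially bound at FDR <= 0.05; 50 lose occupancy in pif4
DEGs: 60 (cdfq) and 60 (pif4); 30 shared (hypergeometric p = 2.19e-09)
50 % of shared DEGs move in opposite directions
Cooperative genes: 10 -> gene_0008, gene_0025, gene_0041, ...
Planted truth recovered: TRUE
```

Reading the output: ~83% of peaks sit within 3 kb upstream of a TSS (80%
was planted; uniform strays add the rest), every upstream metagene bin
clears the randomized null envelope, the recovered spacing modes (27.5
and 17.5 bp bin centers) bracket the planted 25 bp (G-box) and 15 bp
(DOF) means to within one 5 bp histogram bin, binding strength rises
monotonically with planted G-box count (the letter display separates all
four groups), the 50 peaks with planted occupancy loss are recovered at
FDR ≤ 0.05 with the right sign (53 calls, 50 of them down), and the
four-way evidence intersection returns exactly the 10 planted
cooperative genes.

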