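---
title: "Methods: peak architecture and co-regulation analysis with cobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak architecture and co-regulation analysis with cobind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`cobind` analyses how a pair of transcription factors cooperate at shared
genomic targets. The motivating system is a bHLH factor that binds the
palindromic G-box (CACGTG) together with a single zinc-finger DOF factor
whose short core motif ([T/A]AAAG) is too common in plant genomes to
explain target specificity on its own. The package asks, on peak-level
data, the questions such a study needs answered:

1. **Where do peaks sit relative to genes?** Peaks are assigned to every
   gene whose extended span contains the peak anchor — 3 kb upstream of
   the TSS to 1 kb downstream of the TES, in gene orientation, boundaries
   inclusive. Multi-assignment is deliberate: one peak may regulate
   several neighbours, so the peak:gene ratio exceeds one.
2. **Is the positional distribution non-random?** The observed metagene
   profile is compared against an envelope built from randomized peak
   sets that preserve the observed length multiset exactly, placed
   uniformly over the genome.
3. **What motif architecture do peaks carry?** Exact IUPAC consensus
   scanning on both strands, per-peak motif counts, consecutive-motif
   spacing, and a binomial test of central enrichment within peaks.
4. **Does binding strength track motif content?** Peak scores stratified
   by motif count, a tie-corrected Kruskal-Wallis test, pairwise Wilcoxon
   rank-sum tests with BH adjustment, and a compact letter display.
5. **Which peaks lose occupancy when the partner is absent?** A
   normalized, moderated per-peak test at FDR ≤ 0.05.
6. **Which genes are cooperatively regulated?** The intersection of four
   evidence layers: differentially expressed in both mutants, bound by
   both factors, and showing significantly reduced binding of the main
   factor in the partner mutant.

# Coordinate and scanning conventions

All intervals are 0-based half-open internally; GFF3 (1-based closed) is
converted at the I/O boundary and nowhere else. The TSS is the first
transcribed base (`start` on "+", `end - 1` on "−"). Sequences are
uppercased on read, so scanning is case-insensitive; N never matches.
Minus-strand motif matches are reported at their forward-strand start
offset. Palindromic motifs (CACGTG equals its reverse complement) are
reported once, forward only, to avoid double counting. The default count
policy counts overlapping matches ("all"); a greedy left-to-right
non-overlapping policy is available, since published per-peak counts
rarely state which was used.

Spacing is measured start-to-start between consecutive same-motif hits
within a region, match strand ignored, because the field reports single
scalar spacings (25 bp for G-boxes, 15 bp for DOF motifs) without strand
qualification. The spacing histogram uses 5 bp bins: wide enough to
smooth count noise, narrow enough to resolve 15 bp from 25 bp modes; the
mode estimate is the center of the maximal bin, ties broken toward the
smaller distance.

The promoter window for the non-target background is 1,000 bp 5′ of the
TSS. This is a declared default, not an inferred value: background
spacing is only used as a contrast, and the geometric-decay shape of
random-sequence spacing is insensitive to the window within a factor of
a few.

# The metagene axis and the randomized null

The metagene axis concatenates the upstream flank rescaled to [−1, 0),
the gene body rescaled to [0, 1], and the downstream flank rescaled to
(1, 2], with 50 equal bins by default (bins are configuration, not
contract). Each link contributes once, so a doubly assigned peak counts
twice. Densities are normalized by the number of peaks: the profile then
sums to the multi-assignment-weighted fraction of peaks assigned, and —
decisively — planting extra promoter-proximal peaks raises the upstream
density instead of being cancelled by renormalization over links, which
is what makes positional enrichment detectable at all.

Each of the `n_sets` (default 1,000) random sets reproduces the observed
peak-length multiset exactly; for every length the chromosome is chosen
with probability proportional to the number of start positions where the
peak fits and the start uniformly among them. Nothing is blacklisted.
Per-bin means and 2.5/97.5 percentiles across sets form the envelope.
Note that the width of an empirical percentile envelope *grows* with
`n_sets` (from zero at one set toward the population interval), so
envelope width is not a convergence diagnostic; coverage is. When the
observed peaks are themselves uniform, the observed density falls inside
the envelope in ≈95% of bins, provided per-bin counts are large enough
to behave continuously — the calibration experiment therefore uses 3,000
peaks and 800 genes, where measured coverage is ≈0.95–0.96; at a few
links per bin the discrete envelope over-covers (ties at the boundary
count as inside) and coverage drifts toward 0.98.

# Occupancy statistics

**Stratification.** Peaks are grouped by motif count 0, 1, …, with counts
at or above `max_group` (default 3) pooled. Kruskal-Wallis H is computed
from rank sums with the standard tie correction and referred to
chi-square with g−1 df. Pairwise comparisons use the two-sided Wilcoxon
rank-sum normal approximation with tie correction and no continuity
correction; p values are BH-adjusted across pairs (the adjustment is a
declared convention — published legends often say only "pairwise Wilcox
tests"). Letters are assigned by insert-and-absorb, which guarantees
exactly: two groups share a letter ⇔ their adjusted p ≥ α (default
0.05).

**Differential occupancy.** Counts are normalized by median-of-ratios
size factors (library-size ratios as a fallback when no row is positive
in all samples), shifted by a 0.5 pseudocount and log2-transformed, and
each peak is tested between conditions with BH adjustment across peaks;
a peak is significant at FDR ≤ 0.05. The per-peak variance is shrunk
toward an empirical-Bayes prior fitted across peaks by moment matching
on the log variances, and the t reference gains the prior degrees of
freedom. This moderation is not optional polish: with three replicates a
plain Welch test has ≈4 df, its smallest attainable p values are of
order 10^-4 even at |t| = 10, and the BH cascade at FDR 0.05 with ~10%
affected peaks needs p ≈ 10^-3 or smaller — measured sensitivity of the
unmoderated chain, side by side on the same data in the test suite, is a
small fraction of that of the moderated chain, which recovers over 90%
of planted effects at a controlled empirical FDR. The unmoderated Welch
chain is retained
(`moderate = FALSE`) and cross-checked against `t.test`; the moderated
chain is cross-checked against limma on the same data in the test suite.
The 0.5 pseudocount is a standard variance stabilizer for
negative-binomial counts at this scale.

**Co-regulation.** The DEG filter keeps |log2fc| ≥ log2(1.5) (boundary
inclusive) with adjusted p < 0.05 (boundary strict), mirroring the usual
phrasing "1.5-fold change with an adjusted P value < 0.05". Overlap
significance is the hypergeometric upper tail P(X ≥ k); the universe
defaults to the genes present in both DEG tables. Direction consistency
partitions shared DEGs by sign agreement. The cooperative set is the
exact four-way intersection with per-gene provenance; reduced-binding
genes are those linked to peaks significant at FDR ≤ 0.05 with negative
log2fc.

# The synthetic study and its truth bundle

The generator is first-class, tested code: it defines the study
conditions under which every recovery claim is made.

* **Genome**: 2 chromosomes × 2 Mb, i.i.d. uniform base composition.
  Uniform (not AT-rich) composition is a deliberate simplification —
  composition mimicry is out of scope, and motif-planting retry rates
  only improve. The gene density (300 genes, 500–2,000 bp, ≈1 gene per
  13 kb) is chosen sparse enough that a uniformly placed peak is *not*
  almost surely within 3 kb of some TSS; at several-fold higher density
  the assignment windows tile the genome and positional planting becomes
  undetectable in principle.
* **Peaks**: 500 non-overlapping peaks, lengths Normal(300, 60) truncated
  at ≥50 bp; 80% have their center within 3 kb upstream of a random TSS
  (echoing the ~82% upstream share reported for DOF-factor peaks), the
  rest uniform.
* **Motif plan**: per peak, a G-box count drawn with probabilities
  (0.71, 0.20, 0.06, 0.03) over 0–3 (≈20% one G-box, ≈9% more than one)
  and a DOF count with (0.05, 0.08, 0.47, 0.40) (≈87% with ≥2, maximum
  3); consecutive sites are written with start-to-start gaps
  Normal(25, 5) and Normal(15, 4) bp respectively, truncated at motif
  length + 1. After writing, each peak is rescanned with the package
  scanner and redrawn (fresh background and positions, up to 100 times)
  until the scan finds exactly the planted sites — the truth-equals-scan
  guarantee every recovery test relies on. Planting rewrites sequence in
  place, so coordinates never shift.
* **Scores**: expected score linear in the planted G-box count
  (base 2, slope 2, Gaussian noise SD 1, floored at 0.01), giving the
  binding-strength stratification a real monotone signal.
* **Counts**: negative binomial, mean 200, dispersion 0.05, per-sample
  size factors log-uniform in [0.7, 1.4], 3 replicates per genotype. 10%
  of peaks — drawn preferentially from G-box carriers — get a planted
  log2 change of −2.5 in the partner-mutant condition: a strong binding
  loss, consistent with the strong occupancy bias such studies report,
  and large enough that end-to-end gene recovery is limited by the
  statistics, not by an arbitrarily marginal effect.
* **DEG tables**: every gene appears in both genotype tables; 60 DEGs per
  genotype of which 30 are shared; planted DEGs clear the default filter
  with margin, all other genes fail it by construction. One third of the
  shared set (10 genes) is cooperative: drawn from genes linked to
  affected peaks, forced into the partner-bound layer. Non-cooperative
  shared DEGs are drawn outside the reduced-binding layer so the planted
  truth is exactly recoverable; false positives can then arise only from
  false differential-binding calls, which is precisely what the
  end-to-end test measures. Per-genotype DEG directions are
  Bernoulli(frac_up = 0.5) independently, so ≈50% of shared DEGs move in
  opposite directions in expectation; the realized directions are
  recorded in the truth bundle and the direction-consistency module is
  tested against them exactly.

Randomness: every stage derives a fixed sub-seed from the master seed
(genome, peaks, motifs, counts, DEG tables, in that order), so each
generator is deterministic in isolation and the composed dataset is
byte-identical across runs of the same config.

# What the synthetic data does and does not show

The generator reproduces the downstream *statistical structure* the
analyses consume: positional enrichment, motif count and spacing
distributions, overdispersed replicated counts with a condition effect,
and thresholded DEG tables with planted overlap. It does not model reads,
chromatin background, peak-calling artefacts, correlated motif
co-occurrence, or realistic base composition. Passing recovery tests
therefore demonstrates that the pipeline's inference is correct under its
own model assumptions — not that those assumptions capture every property
of real ChIP-seq data.

# Numerical choices and degenerate inputs

* Peak anchors default to the interval center; the summit is used when
  present and requested. Centers are exact under reflection only for
  odd lengths; tests account for this.
* Peaks on chromosomes absent from the gene list are skipped with a
  counted warning; an empty link set yields an empty profile with a
  warning rather than an error.
* A peak with identical replicate values and equal condition means gets
  p = 1; zero variance with unequal means gets p = 0.
* Zero-hit central enrichment returns p = 1; candidate windows wider
  than every peak half-span are skipped with a warning.
* Constant rows z-score to zero with a warning (population SD is used,
  as is conventional for expression heatmaps).
* The hypergeometric upper tail is computed as `phyper(k − 1, …,
  lower.tail = FALSE)`, exact for k = 0 (p = 1).

# Problem sizes

The default study (500 peaks, 300 genes, 4 Mb, 1,000 null sets) runs in
a few seconds. The test suite's simulation-heavy checks use 20–40 seeds
per property, 500–3,000 peaks each; the envelope-calibration experiment
uses 3,000 peaks and 800 genes so that per-bin densities are in the
quasi-continuous regime where a 95% percentile envelope actually covers
at 95%. These sizes are the package's own choices for stable stochastic
assertions.

# Known limitations

* Exact-consensus scanning only: no PWM scores, no de novo discovery.
* The occupancy test is a moderated t on log counts, not a full NB GLM
  with dispersion shrinkage; at very low counts (mean ≪ 10) the log
  transform is a poorer variance stabilizer.
* The randomized positional null excludes nothing (no mappability or
  blacklist model), exactly matching its stated construction.
* The DEG universe is the intersection of the two input tables; studies
  with different detectability per genotype may prefer an explicit
  universe, which the API accepts.
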