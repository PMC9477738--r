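# The synthetic-data generator: determinism, degenerate configurations,
# the truth-equals-scan guarantee for planted motifs, count-model moments,
# and the planted DEG/cooperative structure.

small_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, n_peaks = 80L, n_genes = 40L,
               chrom_length = 300000L,
               deg_plan = list(cdfq = list(n_deg = 15L, frac_up = 0.5),
                               pif4 = list(n_deg = 15L, frac_up = 0.5),
                               n_shared = 8L, overlap_with_bound = 0.25),
               factorB_bound_n = 20L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("identical configs give byte-identical datasets", {
  ds1 <- simulate_dataset(small_cfg(seed = 11))
  ds2 <- simulate_dataset(small_cfg(seed = 11))
  expect_identical(ds1$genome, ds2$genome)
  expect_identical(ds1$peaks, ds2$peaks)
  expect_identical(ds1$counts, ds2$counts)
  expect_identical(ds1$deg_tables, ds2$deg_tables)
  expect_identical(ds1$truth, ds2$truth)
  # different seed changes the data
  expect_false(identical(
    simulate_dataset(small_cfg(seed = 12))$genome, ds1$genome))
})

test_that("degenerate base composition gives a single-letter genome", {
  cfg <- sim_config(seed = 1, n_chrom = 1L, chrom_length = 5000L,
                    n_genes = 3L, gene_length_range = c(100L, 200L),
                    n_peaks = 2L,
                    base_composition = c(A = 1, C = 0, G = 0, T = 0))
  g <- generate_genome(cfg)
  expect_equal(unique(strsplit(g$genome[[1]], "")[[1]]), "A")
})

test_that("impossible gene packing raises a placement error", {
  cfg <- sim_config(seed = 1, n_chrom = 1L, chrom_length = 2000L,
                    n_genes = 10L, gene_length_range = c(400L, 600L),
                    n_peaks = 2L)
  expect_error(generate_genome(cfg), "longer chromosomes")
})

test_that("zero length sd gives equal peak lengths; promoter planting works", {
  cfg <- small_cfg(seed = 2, peak_length_sd = 0, promoter_fraction = 1)
  g <- generate_genome(cfg)
  pk <- generate_peaks(cfg, g$genes)
  lens <- pk$peaks$end - pk$peaks$start
  expect_equal(length(unique(lens)), 1L)
  # every center within 3 kb upstream of some TSS, gene orientation respected
  centers <- pk$peaks$start + lens %/% 2L
  tss <- ifelse(g$genes$strand == "+", g$genes$start, g$genes$end - 1L)
  ok <- vapply(seq_along(centers), function(i) {
    same <- g$genes$chrom == pk$peaks$chrom[i]
    d <- ifelse(g$genes$strand[same] == "+",
                tss[same] - centers[i], centers[i] - tss[same])
    any(d >= 1 & d <= 3000)
  }, TRUE)
  expect_true(all(ok))
})

test_that("planted motifs are exactly what the scanner finds", {
  cfg <- small_cfg(seed = 4)
  ds <- simulate_dataset(cfg)
  for (m in names(cfg$motif_plan)) {
    spec <- motif_spec(m, cfg$motif_plan[[m]]$consensus)
    hits <- scan_peaks(ds$genome, ds$peaks, spec)
    counts <- motif_counts_per_peak(hits, ds$peaks)
    expect_equal(unname(counts), unname(ds$truth$planned_counts[, m]))
    obs <- split(hits$offset, hits$region_id)
    for (id in ds$peaks$id) {
      expect_equal(sort(obs[[id]] %||% integer(0)),
                   sort(ds$truth$motif_positions[[m]][[id]]),
                   info = paste(m, id))
    }
  }
})

test_that("constant spacing plans reproduce exact gaps on rescan", {
  cfg <- small_cfg(
    seed = 5,
    motif_plan = list(gbox = list(consensus = "CACGTG",
                                  count_probs = c(0, 0, 1, 0),
                                  spacing_mean = 25, spacing_sd = 0)))
  ds <- simulate_dataset(cfg)
  hits <- scan_peaks(ds$genome, ds$peaks, motif_spec("gbox", "CACGTG"))
  sp <- spacing_distances(hits)
  expect_true(all(sp$distances == 25L))
  expect_equal(length(sp$distances), nrow(ds$peaks))
})

test_that("a zero-count plan on a motif-free background yields zero hits", {
  cfg <- sim_config(seed = 6, n_chrom = 1L, chrom_length = 60000L,
                    n_genes = 5L, gene_length_range = c(200L, 400L),
                    n_peaks = 10L, promoter_fraction = 0,
                    base_composition = c(A = 0, C = 1, G = 0, T = 0),
                    motif_plan = list(dof = list(consensus = "AAAAG",
                                                 count_probs = c(1, 0),
                                                 spacing_mean = 15,
                                                 spacing_sd = 4)))
  g <- generate_genome(cfg)
  pk <- generate_peaks(cfg, g$genes)
  pl <- plant_motifs(g$genome, pk$peaks, cfg, pk$truth$planned_counts)
  hits <- scan_peaks(pl$genome, pk$peaks, motif_spec("dof", "AAAAG"))
  expect_equal(nrow(hits), 0L)
})

test_that("an unsatisfiable motif plan names the offending peak", {
  cfg <- sim_config(seed = 7, n_chrom = 1L, chrom_length = 100000L,
                    n_genes = 5L, gene_length_range = c(200L, 400L),
                    n_peaks = 3L, promoter_fraction = 0,
                    peak_length_mean = 60, peak_length_sd = 0,
                    motif_plan = list(gbox = list(consensus = "CACGTG",
                                                  count_probs = c(0, 0, 0, 1),
                                                  spacing_mean = 60,
                                                  spacing_sd = 0)))
  g <- generate_genome(cfg)
  pk <- generate_peaks(cfg, g$genes)
  expect_error(plant_motifs(g$genome, pk$peaks, cfg,
                            pk$truth$planned_counts),
               "peak_")
})

test_that("peak scores rise with the planted G-box count", {
  cfg <- sim_config(seed = 8, n_peaks = 400L, n_genes = 100L,
                    chrom_length = 1000000L)
  g <- generate_genome(cfg)
  pk <- generate_peaks(cfg, g$genes)
  k <- pk$truth$planned_counts[, "gbox"]
  means <- tapply(pk$peaks$score, k, mean)
  expect_true(all(diff(means[c("0", "1", "2")]) > 0))
})

test_that("counts follow the NB model and degenerate to Poisson", {
  peaks <- data.frame(id = sprintf("p%05d", 1:10000))
  cfg <- sim_config(seed = 9, affected_fraction = 0, nb_dispersion = 0)
  cm <- simulate_counts(peaks, cfg)
  x <- cm$counts[, 1]
  mu <- mean(x)
  expect_lt(abs(var(x) / mu - 1), 0.05)

  cfg2 <- sim_config(seed = 9, affected_fraction = 0, nb_dispersion = 0.2)
  cm2 <- simulate_counts(peaks, cfg2)
  y <- cm2$counts[, 1]
  # NB variance mu + disp * mu^2, within 15% at n = 10,000
  expect_lt(abs(var(y) / (mean(y) + 0.2 * mean(y)^2) - 1), 0.15)

  # no planted effect: conditions exchangeable after size-factor correction
  l <- sweep(cm$counts, 2, cm$truth$size_factors, "/")
  d <- rowMeans(l[, 4:6]) - rowMeans(l[, 1:3])
  expect_lt(abs(mean(d)) / (sd(d) / sqrt(nrow(l))), 4)

  expect_error(simulate_counts(peaks, sim_config(n_replicates = 1L)),
               "replicates")
})

test_that("affected peaks prefer G-box carriers and carry the planted effect", {
  cfg <- small_cfg(seed = 10, n_peaks = 200L)
  g <- generate_genome(cfg)
  pk <- generate_peaks(cfg, g$genes)
  cm <- simulate_counts(pk$peaks, cfg, pk$truth$planned_counts)
  aff <- cm$truth$affected_peak_ids
  expect_equal(length(aff), round(cfg$affected_fraction * 200))
  expect_true(all(pk$truth$planned_counts[aff, "gbox"] >= 1L))
  expect_equal(unname(cm$truth$true_log2fc[aff]),
               rep(cfg$effect_log2fc, length(aff)))
})

test_that("DEG tables plant exactly the intended sets and directions", {
  ds <- simulate_dataset(small_cfg(seed = 13))
  cfg <- ds$config
  for (g in c("cdfq", "pif4")) {
    filt <- filter_degs(ds$deg_tables[[g]])
    expect_setequal(filt$gene_id, names(ds$truth$deg_sets[[g]]))
    expect_equal(unname(filt$direction),
                 unname(ds$truth$deg_sets[[g]][filt$gene_id]))
  }
  shared <- intersect(names(ds$truth$deg_sets$cdfq),
                      names(ds$truth$deg_sets$pif4))
  expect_setequal(shared, ds$truth$shared_gene_ids)
  expect_equal(length(ds$truth$cooperative_gene_ids),
               round(cfg$deg_plan$overlap_with_bound * cfg$deg_plan$n_shared))
  # cooperative truth lies inside every evidence layer
  expect_true(all(ds$truth$cooperative_gene_ids %in%
                    ds$bound_sets$bound_by_A))
  expect_true(all(ds$truth$cooperative_gene_ids %in%
                    ds$bound_sets$bound_by_B))
  expect_true(all(ds$truth$cooperative_gene_ids %in%
                    ds$bound_sets$reduced_binding))
})

test_that("degenerate DEG plans behave as declared", {
  # overlap_with_bound 0: no cooperative truth
  cfg <- small_cfg(seed = 14)
  cfg$deg_plan$overlap_with_bound <- 0
  ds <- simulate_dataset(cfg)
  expect_equal(length(ds$truth$cooperative_gene_ids), 0L)

  # frac_up 1 in both genotypes: nothing moves in opposite directions
  cfg2 <- small_cfg(seed = 15)
  cfg2$deg_plan$cdfq$frac_up <- 1
  cfg2$deg_plan$pif4$frac_up <- 1
  ds2 <- simulate_dataset(cfg2)
  expect_equal(ds2$truth$fraction_opposite, 0)

  # requested overlap larger than a DEG set errors
  cfg3 <- small_cfg(seed = 16)
  cfg3$deg_plan$n_shared <- 100L
  expect_error(simulate_dataset(cfg3), "overlap larger")
})

test_that("written datasets reload consistently", {
  ds <- simulate_dataset(small_cfg(seed = 17), outdir = td <- tempfile())
  expect_equal(read_fasta(file.path(td, "genome.fa")), ds$genome)
  expect_equal(read_genes(file.path(td, "genes.gff3")), ds$genes)
  pk <- read_peaks(file.path(td, "peaks.narrowPeak"), "narrowPeak")
  expect_equal(pk$start, ds$peaks$start)
  expect_equal(pk$score, ds$peaks$score, tolerance = 1e-6)
  expect_equal(read_count_matrix(file.path(td, "counts.tsv")), ds$counts)
  tr <- jsonlite::read_json(file.path(td, "truth.json"),
                            simplifyVector = TRUE)
  expect_setequal(tr$cooperative_gene_ids, ds$truth$cooperative_gene_ids)
})
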