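# Synthetic regulatory-genome generator with planted ground truth: random
# genome and gene models, peaks enriched upstream of TSSs, planted motif
# architecture (counts and spacings), negative-binomial occupancy counts
# with a planted condition effect, and DEG tables with a planted shared and
# cooperative gene structure.  Every planted quantity is recorded in a truth
# bundle so the analysis modules can be tested against known answers.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: most peaks sit within
#' 3 kb upstream of a TSS; roughly 20\% of peaks carry one G-box and 9\%
#' more than one, with consecutive G-box spacing centered on 25 bp; 87\% of
#' peaks carry two or more DOF motifs (at most three), with spacing centered
#' on 15 bp; occupancy counts are negative-binomial over two genotypes with
#' a strong planted binding-loss effect on a tenth of the peaks; DEG tables
#' for the two mutant genotypes share a planted overlap of which a planted
#' subset is cooperative.
#'
#' @param seed master RNG seed; each generator stage derives a fixed
#'   sub-seed from it.
#' @param n_chrom,chrom_length genome shape.
#' @param base_composition named probabilities for A, C, G, T.
#' @param n_genes,gene_length_range gene models.
#' @param n_peaks,peak_length_mean,peak_length_sd peak set.
#' @param promoter_fraction fraction of peaks whose center is placed within
#'   3 kb upstream of a randomly chosen TSS.
#' @param motif_plan per-motif list: consensus, count_probs (over 0..3),
#'   spacing_mean, spacing_sd (bp, start-to-start).
#' @param score_base,score_slope,score_sd linear score plan: expected peak
#'   score rises with the planted G-box count.
#' @param n_replicates replicates per condition.
#' @param nb_mean,nb_dispersion negative-binomial count model.
#' @param affected_fraction fraction of peaks given the condition effect.
#' @param effect_log2fc planted log2 occupancy change (condition 2 vs 1).
#' @param deg_plan per-genotype n_deg and frac_up, plus n_shared (planted
#'   DEG overlap) and overlap_with_bound (fraction of the shared set that is
#'   also cooperative).
#' @param factorB_bound_n number of genes bound by the partner factor
#'   (cooperative genes are always included).
#' @param max_retries bounded retries for motif planting.
#' @return config list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_length = 2000000L,
                       base_composition = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                       n_genes = 300L, gene_length_range = c(500L, 2000L),
                       n_peaks = 500L, peak_length_mean = 300,
                       peak_length_sd = 60,
                       promoter_fraction = 0.8,
                       motif_plan = list(
                         gbox = list(consensus = "CACGTG",
                                     count_probs = c(0.71, 0.20, 0.06, 0.03),
                                     spacing_mean = 25, spacing_sd = 5),
                         dof = list(consensus = "AAAAG",
                                    count_probs = c(0.05, 0.08, 0.47, 0.40),
                                    spacing_mean = 15, spacing_sd = 4)),
                       score_base = 2, score_slope = 2, score_sd = 1,
                       n_replicates = 3L,
                       nb_mean = 200, nb_dispersion = 0.05,
                       affected_fraction = 0.1, effect_log2fc = -2.5,
                       deg_plan = list(
                         cdfq = list(n_deg = 60L, frac_up = 0.5),
                         pif4 = list(n_deg = 60L, frac_up = 0.5),
                         n_shared = 30L, overlap_with_bound = 1 / 3),
                       factorB_bound_n = 80L,
                       max_retries = 100L) {
  stopifnot(abs(sum(base_composition) - 1) < 1e-8,
            promoter_fraction >= 0, promoter_fraction <= 1,
            affected_fraction >= 0, affected_fraction <= 1,
            n_chrom > 0, chrom_length > 0, n_genes > 0, n_peaks > 0)
  for (m in motif_plan) {
    stopifnot(abs(sum(m$count_probs) - 1) < 1e-8)
  }
  as.list(environment())
}

#' Generate a random genome and non-overlapping gene models
#'
#' Bases are i.i.d. from the configured composition; gene lengths are
#' uniform over the configured range, strands Bernoulli(0.5), placements
#' non-overlapping (bounded retries, then an error suggesting longer
#' chromosomes).  Deterministic given the config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with genome (named character vector) and genes (data.frame).
#' @export
#' @importFrom stats rbinom runif
generate_genome <- function(config) {
  set.seed(stage_seed(config$seed, "genome"))
  chroms <- paste0("chr", seq_len(config$n_chrom))
  genome <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE,
                 prob = config$base_composition), collapse = "")
  }, "")
  lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 config$n_genes, replace = TRUE)
  if (as.numeric(config$n_genes) * max(lens) >
      as.numeric(config$n_chrom) * config$chrom_length) {
    stop("genes cannot fit in the genome; use longer chromosomes")
  }
  placed <- lapply(chroms, function(ch) list(start = integer(), end = integer()))
  names(placed) <- chroms
  rows <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    ok <- FALSE
    for (try in seq_len(500L)) {
      ch <- sample(chroms, 1L, prob = rep(config$chrom_length, length(chroms)))
      start <- floor(stats::runif(1) * (config$chrom_length - lens[i] + 1))
      end <- start + lens[i]
      p <- placed[[ch]]
      if (!any(start < p$end & end > p$start)) {
        placed[[ch]]$start <- c(p$start, start)
        placed[[ch]]$end <- c(p$end, end)
        rows[[i]] <- data.frame(id = sprintf("gene_%04d", i), chrom = ch,
                                start = as.integer(start),
                                end = as.integer(end),
                                strand = if (stats::rbinom(1, 1, 0.5)) "+" else "-",
                                stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place gene ", i,
           " without overlap; use longer chromosomes")
    }
  }
  genes <- do.call(rbind, rows)
  list(genome = genome, genes = genes)
}

# Draw peak lengths: Normal(mean, sd) truncated at >= 50 bp by redraw.
draw_peak_lengths <- function(n, mean, sd) {
  if (sd == 0 && mean < 50) stop("peak length mean below the 50 bp floor")
  lens <- round(stats::rnorm(n, mean, sd))
  for (it in seq_len(1000L)) {
    bad <- lens < 50
    if (!any(bad)) break
    lens[bad] <- round(stats::rnorm(sum(bad), mean, sd))
  }
  lens[lens < 50] <- 50L
  as.integer(lens)
}

#' Generate peaks with planted positional and motif-count structure
#'
#' A \code{promoter_fraction} share of peaks have their center within
#' 3,000 bp upstream of a randomly chosen TSS (gene orientation respected);
#' the remainder are uniform over the genome.  Peaks never overlap one
#' another.  Planned per-peak motif counts are drawn here so the score plan
#' can couple to them: expected score is linear in the planted G-box count.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genes gene data.frame from \code{\link{generate_genome}}.
#' @return list with peaks (data.frame) and truth (promoter_peak_ids,
#'   planned_counts matrix, score plan).
#' @export
#' @importFrom stats rnorm
generate_peaks <- function(config, genes) {
  set.seed(stage_seed(config$seed, "peaks"))
  n <- config$n_peaks
  lens <- draw_peak_lengths(n, config$peak_length_mean, config$peak_length_sd)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  chrom_len <- stats::setNames(rep(config$chrom_length, config$n_chrom), chroms)
  n_prom <- ceiling(config$promoter_fraction * n)
  placed <- lapply(chroms, function(ch) list(start = integer(), end = integer()))
  names(placed) <- chroms
  tss <- gene_tss(genes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      if (i <= n_prom) {
        g <- sample.int(nrow(genes), 1L)
        d <- sample.int(3000L, 1L)
        center <- if (genes$strand[g] == "+") tss[g] - d else tss[g] + d
        ch <- genes$chrom[g]
        start <- center - lens[i] %/% 2L
      } else {
        ch <- sample(chroms, 1L, prob = chrom_len - lens[i] + 1)
        start <- floor(stats::runif(1) * (chrom_len[ch] - lens[i] + 1))
      }
      end <- start + lens[i]
      if (start < 0 || end > chrom_len[ch]) next
      p <- placed[[ch]]
      if (any(start < p$end & end > p$start)) next
      placed[[ch]]$start <- c(p$start, start)
      placed[[ch]]$end <- c(p$end, end)
      rows[[i]] <- data.frame(id = sprintf("peak_%04d", i), chrom = ch,
                              start = as.integer(start), end = as.integer(end),
                              strand = ".", stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place peak ", i, " without overlap")
  }
  peaks <- do.call(rbind, rows)
  motifs <- names(config$motif_plan)
  planned <- matrix(0L, nrow = n, ncol = length(motifs),
                    dimnames = list(peaks$id, motifs))
  for (m in motifs) {
    probs <- config$motif_plan[[m]]$count_probs
    planned[, m] <- sample(seq_along(probs) - 1L, n, replace = TRUE,
                           prob = probs)
  }
  k_gbox <- if ("gbox" %in% motifs) planned[, "gbox"] else 0L
  score <- pmax(config$score_base + config$score_slope * k_gbox +
                  stats::rnorm(n, 0, config$score_sd), 0.01)
  peaks$score <- score
  peaks$summit_offset <- NA_integer_
  truth <- list(promoter_peak_ids = peaks$id[seq_len(n_prom)],
                planned_counts = planned,
                score_plan = list(base = config$score_base,
                                  slope = config$score_slope,
                                  sd = config$score_sd))
  list(peaks = peaks, truth = truth)
}

# Instantiate an IUPAC consensus as a concrete sequence (degenerate codes
# resolved uniformly at random).
instantiate_consensus <- function(consensus) {
  expand <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))
  chars <- strsplit(consensus, "")[[1]]
  paste(vapply(chars, function(c) {
    opts <- expand[[c]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

# Draw planted site offsets for one peak: per motif, (k - 1) start-to-start
# gaps from the spacing distribution (truncated >= motif length + 1), a
# uniform first offset, all sites non-overlapping across motifs.  Returns
# NULL when the draw cannot fit.
draw_peak_sites <- function(peak_len, planned_k, plan) {
  occupied <- matrix(numeric(0), ncol = 2)
  sites <- list()
  for (m in names(plan)) {
    k <- planned_k[[m]]
    if (k == 0L) {
      sites[[m]] <- integer(0)
      next
    }
    mlen <- nchar(plan[[m]]$consensus)
    gaps <- integer(0)
    if (k > 1L) {
      gaps <- round(stats::rnorm(k - 1L, plan[[m]]$spacing_mean,
                                 plan[[m]]$spacing_sd))
      for (it in seq_len(200L)) {
        bad <- gaps < mlen + 1L
        if (!any(bad)) break
        gaps[bad] <- round(stats::rnorm(sum(bad), plan[[m]]$spacing_mean,
                                        plan[[m]]$spacing_sd))
      }
      gaps <- pmax(gaps, mlen + 1L)
    }
    span <- sum(gaps) + mlen
    if (span > peak_len) return(NULL)
    placed <- FALSE
    for (it in seq_len(50L)) {
      first <- sample.int(peak_len - span + 1L, 1L) - 1L
      pos <- first + cumsum(c(0L, gaps))
      iv <- cbind(pos, pos + mlen)
      clash <- nrow(occupied) > 0 &&
        any(outer(iv[, 1], occupied[, 2], "<") &
              outer(iv[, 2], occupied[, 1], ">"))
      if (!clash) {
        occupied <- rbind(occupied, iv)
        sites[[m]] <- as.integer(pos)
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  sites
}

#' Plant motif sites into peak sequences
#'
#' Rewrites each peak's sequence in place (coordinates never shift): the
#' peak background is redrawn from the base composition, planned sites are
#' written with start-to-start gaps from the spacing distribution, and the
#' peak is rescanned with the package scanner; if scanning finds any match
#' of a planned motif beyond the planted ones (or misses one), the peak is
#' redrawn, up to \code{max_retries} times, then an error names the peak.
#' The guarantee that truth equals scan is what the recovery tests rely on.
#'
#' @param genome named character vector from \code{\link{generate_genome}}.
#' @param peaks peak data.frame from \code{\link{generate_peaks}}.
#' @param config a \code{\link{sim_config}}.
#' @param planned_counts planned per-peak count matrix (from the peak
#'   truth).
#' @return list with genome (modified), truth (motif_positions: per motif, a
#'   list of planted offsets per peak).
#' @export
plant_motifs <- function(genome, peaks, config, planned_counts) {
  set.seed(stage_seed(config$seed, "motifs"))
  plan <- config$motif_plan
  specs <- lapply(names(plan), function(m) motif_spec(m, plan[[m]]$consensus))
  names(specs) <- names(plan)
  bases <- c("A", "C", "G", "T")
  n <- nrow(peaks)
  positions <- lapply(plan, function(x) {
    stats::setNames(vector("list", n), peaks$id)
  })
  pending <- seq_len(n)
  seqs <- stats::setNames(character(n), peaks$id)
  for (round in seq_len(config$max_retries)) {
    if (!length(pending)) break
    for (i in pending) {
      len <- peaks$end[i] - peaks$start[i]
      bg <- paste(sample(bases, len, replace = TRUE,
                         prob = config$base_composition), collapse = "")
      planned_k <- stats::setNames(as.integer(planned_counts[i, ]),
                                   colnames(planned_counts))
      sites <- draw_peak_sites(len, planned_k, plan)
      if (is.null(sites)) {
        stop("cannot satisfy motif plan inside peak ", peaks$id[i],
             " (length ", len, ")")
      }
      for (m in names(sites)) {
        for (pos in sites[[m]]) {
          site <- instantiate_consensus(plan[[m]]$consensus)
          substr(bg, pos + 1L, pos + nchar(site)) <- site
        }
        positions[[m]][[peaks$id[i]]] <- sites[[m]]
      }
      seqs[i] <- bg
    }
    # batch rescan the peaks written this round; keep failures for redraw
    still <- integer(0)
    for (m in names(plan)) {
      hits <- scan_regions(seqs[pending], specs[[m]])
      obs <- split(hits$offset, hits$region_id)
      for (i in pending) {
        got <- sort(obs[[peaks$id[i]]] %||% integer(0))
        want <- sort(positions[[m]][[peaks$id[i]]])
        if (!identical(as.integer(got), as.integer(want))) {
          still <- c(still, i)
        }
      }
    }
    pending <- sort(unique(still))
    if (round == config$max_retries && length(pending)) {
      stop("could not plant motifs cleanly in peak ",
           peaks$id[pending[1]], " after ", config$max_retries, " retries")
    }
  }
  # splice the final peak sequences back into the chromosomes
  for (ch in unique(peaks$chrom)) {
    s <- genome[[ch]]
    for (i in which(peaks$chrom == ch)) {
      substr(s, peaks$start[i] + 1L, peaks$end[i]) <- seqs[i]
    }
    genome[[ch]] <- s
  }
  list(genome = genome, truth = list(motif_positions = positions))
}

#' Simulate replicated occupancy counts with a planted condition effect
#'
#' Counts are negative binomial with mean nb_mean * sizefactor_j *
#' 2^(delta_i), where delta_i equals \code{effect_log2fc} in condition 2
#' for the affected fraction of peaks and 0 otherwise.  Affected peaks are
#' drawn preferentially from peaks planted with at least one G-box
#' (emulating partner-dependent binding).  Per-sample size factors are
#' log-uniform in [0.7, 1.4].
#'
#' @param peaks peak data.frame.
#' @param config a \code{\link{sim_config}}.
#' @param planned_counts planned motif-count matrix (for the G-box
#'   preference); NULL disables the preference.
#' @param conditions length-2 condition labels.
#' @return list with counts (matrix), condition_of (named vector), truth
#'   (affected_peak_ids, true_log2fc, size_factors).
#' @export
#' @importFrom stats rnbinom rpois
simulate_counts <- function(peaks, config, planned_counts = NULL,
                            conditions = c("wt", "pif4")) {
  if (config$n_replicates < 2L) stop("need at least 2 replicates per condition")
  set.seed(stage_seed(config$seed, "counts"))
  n <- nrow(peaks)
  n_aff <- round(config$affected_fraction * n)
  pool <- peaks$id
  affected <- character(0)
  if (!is.null(planned_counts) && "gbox" %in% colnames(planned_counts)) {
    with_gbox <- peaks$id[planned_counts[peaks$id, "gbox"] >= 1L]
    if (n_aff > 0 && length(with_gbox) < n_aff) {
      affected <- with_gbox
      pool <- setdiff(peaks$id, with_gbox)
    } else {
      pool <- with_gbox
    }
  }
  n_left <- n_aff - length(affected)
  if (n_left > 0) affected <- c(affected, sample(pool, n_left))
  delta <- stats::setNames(numeric(n), peaks$id)
  delta[affected] <- config$effect_log2fc
  samples <- paste0(rep(conditions, each = config$n_replicates), "_rep",
                    rep(seq_len(config$n_replicates), 2))
  condition_of <- stats::setNames(rep(conditions, each = config$n_replicates),
                                  samples)
  sf <- exp(stats::runif(length(samples), log(0.7), log(1.4)))
  names(sf) <- samples
  counts <- matrix(0L, nrow = n, ncol = length(samples),
                   dimnames = list(peaks$id, samples))
  for (j in seq_along(samples)) {
    mu <- config$nb_mean * sf[j] *
      2^(delta * (condition_of[j] == conditions[2]))
    counts[, j] <- if (config$nb_dispersion > 0) {
      stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(n, mu)
    }
  }
  list(counts = counts, condition_of = condition_of,
       truth = list(affected_peak_ids = sort(affected),
                    true_log2fc = delta, size_factors = sf))
}

#' Simulate per-genotype DEG tables with planted shared and cooperative sets
#'
#' Every gene appears in both tables.  Planted DEGs pass the default filter
#' (|log2fc| >= log2(1.5), padj < 0.05) with margin; all other genes fail
#' it.  A planted overlap of the two DEG sets is drawn, of which a planted
#' cooperative subset lies inside bound-by-A AND reduced-binding genes (and
#' is forced into the bound-by-B set); the remaining shared genes are drawn
#' outside the reduced-binding layer so the cooperative truth is exactly
#' recoverable.  Per-genotype directions are Bernoulli(frac_up).
#'
#' @param genes gene data.frame.
#' @param bound_sets list with bound_by_A (gene ids linked to peaks) and
#'   reduced_binding (gene ids linked to affected peaks).
#' @param config a \code{\link{sim_config}}.
#' @return list with deg_tables (named list of data.frames), bound_by_B,
#'   truth (deg sets with directions, shared_gene_ids,
#'   cooperative_gene_ids, opposite fraction).
#' @export
#' @importFrom stats rexp
simulate_deg_tables <- function(genes, bound_sets, config) {
  set.seed(stage_seed(config$seed, "degs"))
  plan <- config$deg_plan
  genotypes <- setdiff(names(plan), c("n_shared", "overlap_with_bound"))
  stopifnot(length(genotypes) == 2L)
  n_shared <- plan$n_shared
  n_coop <- round(plan$overlap_with_bound * n_shared)
  for (g in genotypes) {
    if (n_shared > plan[[g]]$n_deg) {
      stop("requested DEG overlap larger than the ", g, " DEG set")
    }
  }
  pool_coop <- intersect(bound_sets$reduced_binding, bound_sets$bound_by_A)
  if (n_coop > length(pool_coop)) {
    stop("not enough reduced-binding bound genes to plant ", n_coop,
         " cooperative genes (have ", length(pool_coop), ")")
  }
  coop <- if (n_coop > 0) sort(sample(pool_coop, n_coop)) else character(0)
  bound_by_B <- sort(union(sample(genes$id, min(config$factorB_bound_n,
                                                nrow(genes))), coop))
  # non-cooperative shared DEGs avoid the reduced-binding layer entirely
  pool_shared <- setdiff(genes$id, bound_sets$reduced_binding)
  pool_shared <- setdiff(pool_shared, coop)
  if (n_shared - n_coop > length(pool_shared)) {
    stop("not enough genes outside the reduced-binding layer for the shared set")
  }
  shared <- sort(c(coop, sample(pool_shared, n_shared - n_coop)))
  remaining <- setdiff(genes$id, shared)
  deg_sets <- list()
  for (g in genotypes) {
    n_extra <- plan[[g]]$n_deg - n_shared
    extra <- sample(remaining, n_extra)
    remaining <- setdiff(remaining, extra)
    ids <- c(shared, extra)
    dirs <- ifelse(stats::runif(length(ids)) < plan[[g]]$frac_up, 1, -1)
    deg_sets[[g]] <- stats::setNames(dirs, ids)
  }
  thr <- log2(1.5)
  tables <- lapply(genotypes, function(g) {
    set <- deg_sets[[g]]
    is_deg <- genes$id %in% names(set)
    lfc <- stats::runif(nrow(genes), -0.9, 0.9) * thr
    padj <- stats::runif(nrow(genes))
    idx <- match(genes$id[is_deg], names(set))
    lfc[is_deg] <- set[idx] * (thr * 1.01 + stats::rexp(sum(is_deg), 2))
    padj[is_deg] <- stats::runif(sum(is_deg), 0, 0.049)
    data.frame(gene_id = genes$id, log2fc = lfc, padj = padj,
               stringsAsFactors = FALSE)
  })
  names(tables) <- genotypes
  d1 <- deg_sets[[1]][shared]
  d2 <- deg_sets[[2]][shared]
  list(deg_tables = tables, bound_by_B = bound_by_B,
       truth = list(deg_sets = deg_sets,
                    shared_gene_ids = shared,
                    cooperative_gene_ids = coop,
                    n_opposite = sum(d1 * d2 < 0),
                    fraction_opposite = if (length(shared)) {
                      sum(d1 * d2 < 0) / length(shared)
                    } else NA_real_))
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Runs the generator stages in fixed order (genome, peaks, motifs, counts,
#' DEG tables) from one master seed; with an \code{outdir}, writes FASTA,
#' GFF3, BED6, narrowPeak, counts TSV, sample table, per-genotype DEG TSVs
#' and a JSON truth file.  Byte-identical outputs for identical configs.
#'
#' @param config a \code{\link{sim_config}}.
#' @param outdir optional output directory.
#' @param annotation the \code{\link{annotation_config}} used to derive the
#'   bound-gene truth layers.
#' @return list with genome, genes, peaks, counts, condition_of, deg_tables,
#'   bound_sets, links, truth, config.
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL,
                             annotation = annotation_config()) {
  g <- generate_genome(config)
  pk <- generate_peaks(config, g$genes)
  pl <- plant_motifs(g$genome, pk$peaks, config, pk$truth$planned_counts)
  cm <- simulate_counts(pk$peaks, config, pk$truth$planned_counts)
  links <- assign_peaks_to_genes(pk$peaks, g$genes, annotation)
  bound_by_A <- sort(unique(links$gene_id))
  reduced <- sort(unique(links$gene_id[links$peak_id %in%
                                         cm$truth$affected_peak_ids]))
  dg <- simulate_deg_tables(g$genes,
                            list(bound_by_A = bound_by_A,
                                 reduced_binding = reduced),
                            config)
  truth <- c(pk$truth, pl$truth, cm$truth, dg$truth,
             list(bound_by_A = bound_by_A, bound_by_B = dg$bound_by_B,
                  reduced_binding_genes = reduced))
  out <- list(genome = pl$genome, genes = g$genes, peaks = pk$peaks,
              counts = cm$counts, condition_of = cm$condition_of,
              deg_tables = dg$deg_tables,
              bound_sets = list(bound_by_A = bound_by_A,
                                bound_by_B = dg$bound_by_B,
                                reduced_binding = reduced),
              links = links, truth = truth, config = config)
  if (!is.null(outdir)) write_dataset(out, outdir)
  out
}

#' Write a simulated dataset to disk
#' @param dataset result of \code{\link{simulate_dataset}}.
#' @param outdir output directory (created if needed).
#' @return outdir, invisibly.
#' @export
#' @importFrom jsonlite write_json
write_dataset <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$genome, file.path(outdir, "genome.fa"))
  write_genes(dataset$genes, file.path(outdir, "genes.gff3"))
  write_peaks(dataset$peaks, file.path(outdir, "peaks.bed"), "bed6")
  write_peaks(dataset$peaks, file.path(outdir, "peaks.narrowPeak"),
              "narrowPeak")
  write_count_matrix(dataset$counts, file.path(outdir, "counts.tsv"))
  utils::write.table(
    data.frame(sample = names(dataset$condition_of),
               condition = unname(dataset$condition_of)),
    file.path(outdir, "samples.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (g in names(dataset$deg_tables)) {
    write_deg_table(dataset$deg_tables[[g]],
                    file.path(outdir, paste0("deg_", g, ".tsv")))
  }
  # the partner factor's target-gene list (an input layer, not truth)
  utils::write.table(
    data.frame(gene_id = dataset$bound_sets$bound_by_B),
    file.path(outdir, "partner_targets.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tr <- dataset$truth
  tr$planned_counts <- as.data.frame(tr$planned_counts)
  jsonlite::write_json(tr, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
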