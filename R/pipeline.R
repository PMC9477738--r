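# End-to-end orchestration: one config drives simulate -> annotate ->
# motifs -> stratify -> diffbind -> coregulate, with every stage's tables
# written before the next starts and a machine-readable JSON run report.
# The analysis/ scripts in the repository are thin narrative drivers over
# these functions.

#' Pipeline configuration
#'
#' Either a simulation config (simulate-first run) or paths to existing
#' genome/genes/peaks/counts/DEG inputs, plus the analysis settings.
#' Thresholds default to the study conventions: differential-binding
#' FDR <= 0.05, DEG filter 1.5-fold with adjusted p < 0.05, alpha 0.05 for
#' the letter display, 1,000 random sets for the null envelope.
#'
#' @param sim a \code{\link{sim_config}} for simulate-first runs, or NULL.
#' @param paths named list of input paths (genome, genes, peaks, counts,
#'   samples, deg tables) when not simulating.
#' @param annotation an \code{\link{annotation_config}}.
#' @param motifs named list of \code{\link{motif_spec}}s to scan.
#' @param fdr_threshold differential-binding FDR threshold.
#' @param deg_filter a \code{\link{deg_filter_config}}.
#' @param alpha significance level for the letter display.
#' @param n_sets random peak sets for the null envelope.
#' @param bins metagene bins.
#' @param max_group motif-count pooling threshold for stratification.
#' @param seed seed for the stochastic stages.
#' @return config list.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            annotation = annotation_config(),
                            motifs = builtin_motifs()[c("gbox", "dof")],
                            fdr_threshold = 0.05,
                            deg_filter = deg_filter_config(),
                            alpha = 0.05, n_sets = 1000L, bins = 50L,
                            max_group = 3L, seed = 1L) {
  as.list(environment())
}

#' Validate a pipeline configuration
#'
#' Checks every invariant at once and returns all violations; an empty
#' character vector means the config is valid.  Accepts a config list or a
#' path to a YAML/JSON config file.
#'
#' @param config pipeline config list or file path.
#' @return character vector of violations (empty when ok).
#' @export
#' @importFrom yaml read_yaml
validate_config <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(
      if (grepl("\\.json$", config)) {
        jsonlite::read_json(config, simplifyVector = TRUE)
      } else {
        yaml::read_yaml(config)
      },
      error = function(e) stop("cannot parse config file: ",
                               conditionMessage(e)))
  }
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(!is.null(config$sim) || !is.null(config$paths),
      "either a simulation config or input paths must be given")
  if (!is.null(config$paths)) {
    for (p in unlist(config$paths)) {
      chk(file.exists(p), paste0("input file not found: ", p))
    }
  }
  fdr <- config$fdr_threshold %||% 0.05
  chk(is.numeric(fdr) && fdr > 0 && fdr <= 1, "fdr must be in (0,1]")
  alpha <- config$alpha %||% 0.05
  chk(is.numeric(alpha) && alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  n_sets <- config$n_sets %||% 1000L
  chk(is.numeric(n_sets) && n_sets >= 1, "n_sets must be >= 1")
  seed <- config$seed %||% 1L
  chk(is.numeric(seed) && seed >= 0, "seed must be a non-negative integer")
  if (!is.null(config$deg_filter)) {
    chk(config$deg_filter$fold_change_threshold > 0,
        "fold_change_threshold must be > 0")
    chk(config$deg_filter$padj_threshold > 0 &&
          config$deg_filter$padj_threshold <= 1,
        "padj_threshold must be in (0,1]")
  }
  v
}

load_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed %||% sim$seed
    ds <- simulate_dataset(sim, annotation = config$annotation)
    return(ds)
  }
  p <- config$paths
  genome <- read_fasta(p$genome)
  genes <- read_genes(p$genes)
  peaks <- read_peaks(p$peaks, dialect = p$peaks_dialect %||% "bed6")
  counts <- NULL
  condition_of <- NULL
  if (!is.null(p$counts)) {
    counts <- read_count_matrix(p$counts)
    st <- utils::read.delim(p$samples, stringsAsFactors = FALSE)
    condition_of <- stats::setNames(st$condition, st$sample)
  }
  deg_tables <- NULL
  if (!is.null(p$deg_tables)) {
    deg_tables <- lapply(p$deg_tables, read_deg_table)
  }
  bound_sets <- NULL
  if (!is.null(p$partner_targets)) {
    bound_sets <- list(
      bound_by_B = utils::read.delim(p$partner_targets,
                                     stringsAsFactors = FALSE)$gene_id)
  }
  list(genome = genome, genes = genes, peaks = peaks, counts = counts,
       condition_of = condition_of, deg_tables = deg_tables,
       bound_sets = bound_sets, truth = NULL)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full co-binding analysis pipeline
#'
#' Stage order: simulate (optional), annotate, motifs, stratify, diffbind,
#' coregulate, report.  Each stage's outputs are written under
#' \code{outdir} before the next starts; stages without inputs (e.g.
#' diffbind without a count matrix) are skipped and flagged in the report.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param outdir output directory.
#' @return the run report (also written as report.json), invisibly
#'   containing per-stage summaries, seed and config echo.
#' @export
run_all <- function(config = pipeline_config(), outdir = tempfile("cobind_")) {
  violations <- validate_config(config)
  if (length(violations)) {
    stop("invalid config:\n  ", paste(violations, collapse = "\n  "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed,
                 version = as.character(utils::packageVersion("cobind")),
                 stages = list())
  data <- load_inputs(config)
  if (!is.null(config$sim)) {
    write_dataset(data, file.path(outdir, "simulated"))
    report$stages$simulate <- list(
      n_peaks = nrow(data$peaks), n_genes = nrow(data$genes),
      n_chrom = length(data$genome))
  }

  # annotate
  links <- assign_peaks_to_genes(data$peaks, data$genes, config$annotation)
  write_tsv(links, file.path(outdir, "links.tsv"))
  profile <- metagene_profile(data$peaks, data$genes, links,
                              bins = config$bins, config = config$annotation)
  chrom_sizes <- stats::setNames(nchar(data$genome), names(data$genome))
  envelope <- random_peak_null(data$peaks, chrom_sizes, data$genes,
                               config$annotation, n_sets = config$n_sets,
                               seed = config$seed, bins = config$bins)
  write_tsv(data.frame(bin_lo = profile$bin_edges[-length(profile$bin_edges)],
                       bin_hi = profile$bin_edges[-1],
                       observed = profile$density,
                       null_mean = envelope$mean,
                       null_lo95 = envelope$lo95,
                       null_hi95 = envelope$hi95),
            file.path(outdir, "metagene_profile.tsv"))
  report$stages$annotate <- list(
    n_links = nrow(links),
    n_peaks_linked = length(unique(links$peak_id)),
    n_genes_linked = length(unique(links$gene_id)),
    pct_upstream_3kb = 100 * mean(data$peaks$id %in%
                                    links$peak_id[links$category == "upstream"]))

  # motifs
  peak_seqs <- region_sequences(data$genome, data$peaks)
  hits_all <- list()
  counts_per_peak <- list()
  for (m in names(config$motifs)) {
    hits <- scan_regions(peak_seqs, config$motifs[[m]])
    hits_all[[m]] <- hits
    counts_per_peak[[m]] <- motif_counts_per_peak(hits, data$peaks)
  }
  write_tsv(do.call(rbind, hits_all), file.path(outdir, "motif_hits.tsv"))
  spacing <- lapply(hits_all, spacing_distances)
  target_genes <- unique(links$gene_id)
  bg <- lapply(config$motifs, function(spec) {
    background_spacing(data$genes, target_genes, data$genome, spec)
  })
  central <- lapply(names(config$motifs), function(m) {
    cbind(motif = m,
          central_enrichment(hits_all[[m]], data$peaks, config$motifs[[m]]))
  })
  write_tsv(do.call(rbind, central), file.path(outdir, "central_enrichment.tsv"))
  report$stages$motifs <- lapply(names(config$motifs), function(m) {
    freq <- count_frequency(counts_per_peak[[m]])
    list(n_hits = nrow(hits_all[[m]]),
         count_frequency = stats::setNames(freq$n_peaks, freq$k),
         spacing_mode_bp = spacing[[m]]$mode_estimate,
         background_spacing_mode_bp = bg[[m]]$mode_estimate)
  })
  names(report$stages$motifs) <- names(config$motifs)

  # stratify binding strength by motif count (first configured motif)
  strat_motif <- names(config$motifs)[1]
  groups <- stratify_by_motif_count(data$peaks, counts_per_peak[[strat_motif]],
                                    max_group = config$max_group)
  strata <- if (length(groups) >= 2L) {
    pairwise_letters(groups, alpha = config$alpha)
  } else NULL
  if (!is.null(strata)) {
    write_tsv(strata$pairwise, file.path(outdir, "strata_pairwise.tsv"))
    report$stages$stratify <- list(motif = strat_motif,
                                   kw_H = strata$kw_H, kw_p = strata$kw_p,
                                   letters = as.list(strata$letters))
  } else {
    report$stages$stratify <- list(skipped = "fewer than 2 motif-count groups")
  }

  # differential binding
  db <- NULL
  if (!is.null(data$counts)) {
    db <- differential_binding(data$counts, data$condition_of,
                               fdr_threshold = config$fdr_threshold)
    write_tsv(db, file.path(outdir, "diffbind.tsv"))
    report$stages$diffbind <- list(
      n_peaks = nrow(db), n_significant = sum(db$significant),
      n_significant_down = sum(db$significant & db$log2fc < 0))
  } else {
    report$stages$diffbind <- list(skipped = "no counts")
  }

  # coregulation
  if (!is.null(data$deg_tables) && length(data$deg_tables) == 2L) {
    filtered <- lapply(data$deg_tables, filter_degs, config = config$deg_filter)
    shared <- intersect(filtered[[1]]$gene_id, filtered[[2]]$gene_id)
    universe <- intersect(data$deg_tables[[1]]$gene_id,
                          data$deg_tables[[2]]$gene_id)
    ov <- overlap_test(filtered[[1]]$gene_id, filtered[[2]]$gene_id, universe)
    dir <- direction_consistency(filtered[[1]], filtered[[2]])
    bound_A <- unique(links$gene_id)
    bound_B <- data$bound_sets$bound_by_B %||% character(0)
    reduced <- character(0)
    if (!is.null(db)) {
      red_peaks <- db$peak_id[db$significant & db$log2fc < 0]
      reduced <- unique(links$gene_id[links$peak_id %in% red_peaks])
    }
    coop <- cooperative_genes(shared, bound_A, bound_B, reduced)
    write_tsv(coop$provenance, file.path(outdir, "cooperative_genes.tsv"))
    report$stages$coregulate <- list(
      n_deg = stats::setNames(lapply(filtered, nrow), names(filtered)),
      n_shared = length(shared), overlap_p = ov$p,
      n_opposite = dir$n_opposite,
      fraction_opposite = dir$fraction_opposite,
      n_reduced_binding_genes = length(reduced),
      n_cooperative = length(coop$gene_ids),
      cooperative_gene_ids = coop$gene_ids)
  } else {
    report$stages$coregulate <- list(skipped = "need two DEG tables")
  }

  report$config_echo <- serialize_config(config)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}

# Config echo for the report: drop function objects, keep plain values.
serialize_config <- function(config) {
  strip <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) return(Filter(Negate(is.null), lapply(x, strip)))
    x
  }
  strip(config)
}
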