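# Peak-to-gene assignment, metagene positional profiles, and the randomized
# length-matched peak-set null envelope.

#' Annotation configuration
#'
#' Windows follow the convention of assigning a peak to every gene whose
#' extended span it falls in: \code{upstream_window} bp 5' of the TSS and
#' \code{downstream_window} bp 3' of the TES, in gene orientation.
#'
#' @param upstream_window bp upstream of the TSS (default 3000).
#' @param downstream_window bp downstream of the TES (default 1000).
#' @param anchor "center" (default) or "summit" (falls back to center for
#'   peaks without a recorded summit).
#' @return list of class settings.
#' @export
annotation_config <- function(upstream_window = 3000L,
                              downstream_window = 1000L,
                              anchor = c("center", "summit")) {
  anchor <- match.arg(anchor)
  stopifnot(upstream_window >= 0, downstream_window >= 0)
  list(upstream_window = as.integer(upstream_window),
       downstream_window = as.integer(downstream_window),
       anchor = anchor)
}

# TSS/TES genomic positions (0-based) respecting strand.
gene_tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end - 1L)
gene_tes <- function(genes) ifelse(genes$strand == "+", genes$end - 1L, genes$start)

#' Assign peaks to neighbouring genes
#'
#' A link is emitted for EVERY gene whose window (TSS - upstream_window to
#' TES + downstream_window, in gene orientation, boundaries inclusive)
#' contains the peak anchor — multi-assignment is deliberate, so one peak can
#' map to several genes.  Signed distance runs anchor to TSS in gene
#' orientation, negative upstream.  Category is "upstream" strictly 5' of
#' the TSS, "downstream" strictly 3' of the TES, otherwise "genic".
#'
#' @param peaks peak data.frame.
#' @param genes gene data.frame.
#' @param config an \code{\link{annotation_config}}.
#' @return data.frame with columns peak_id, gene_id, category,
#'   signed_distance.  Peaks on chromosomes absent from the gene list are
#'   skipped with a warning giving their count.
#' @export
#' @importFrom IRanges IRanges findOverlaps
assign_peaks_to_genes <- function(peaks, genes, config = annotation_config()) {
  anchor <- peak_anchor(peaks, config$anchor)
  plus <- genes$strand == "+"
  tss <- gene_tss(genes)
  tes <- gene_tes(genes)
  lo <- ifelse(plus, tss - config$upstream_window, tes - config$downstream_window)
  hi <- ifelse(plus, tes + config$downstream_window, tss + config$upstream_window)
  unknown <- !peaks$chrom %in% genes$chrom
  if (any(unknown)) {
    warning(sum(unknown), " peak(s) on chromosomes without genes were skipped")
  }
  links <- vector("list", 0L)
  for (ch in unique(genes$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(pi) || !length(gi)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(anchor[pi], anchor[pi]),
      IRanges::IRanges(lo[gi], hi[gi]))
    if (!length(ov)) next
    p <- pi[S4Vectors_from(ov)]
    g <- gi[S4Vectors_to(ov)]
    sd <- ifelse(genes$strand[g] == "+", anchor[p] - tss[g], tss[g] - anchor[p])
    gene_end_dist <- ifelse(genes$strand[g] == "+",
                            anchor[p] - tes[g], tes[g] - anchor[p])
    category <- ifelse(sd < 0, "upstream",
                       ifelse(gene_end_dist > 0, "downstream", "genic"))
    links[[length(links) + 1L]] <- data.frame(
      peak_id = peaks$id[p], gene_id = genes$id[g],
      category = category, signed_distance = as.integer(sd),
      stringsAsFactors = FALSE)
  }
  if (!length(links)) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      category = character(), signed_distance = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, links)
  out <- out[order(match(out$peak_id, peaks$id),
                   match(out$gene_id, genes$id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Thin wrappers so the IRanges Hits accessors stay in one place.
S4Vectors_from <- function(ov) as.integer(methods::slot(ov, "from"))
S4Vectors_to <- function(ov) as.integer(methods::slot(ov, "to"))

# Metagene coordinate of each link on a normalized axis:
# upstream flank -> [-1, 0), gene body -> [0, 1], downstream flank -> (1, 2].
metagene_coords <- function(anchor, gidx, genes, config) {
  plus <- genes$strand[gidx] == "+"
  tss <- gene_tss(genes)[gidx]
  tes <- gene_tes(genes)[gidx]
  sdist <- ifelse(plus, anchor - tss, tss - anchor)
  ddist <- ifelse(plus, anchor - tes, tes - anchor)
  body_len <- pmax(genes$end[gidx] - genes$start[gidx] - 1L, 1L)
  x <- numeric(length(anchor))
  up <- sdist < 0
  down <- ddist > 0
  body <- !up & !down
  x[up] <- sdist[up] / config$upstream_window
  x[down] <- 1 + ddist[down] / config$downstream_window
  x[body] <- sdist[body] / body_len[body]
  x
}

#' Metagene positional profile of peaks
#'
#' Each link contributes once (a peak linked to two genes is counted twice;
#' this matches the multi-assignment contract).  The axis concatenates the
#' upstream flank (rescaled to [-1, 0)), the gene body (rescaled to [0, 1])
#' and the downstream flank ((1, 2]); densities are normalized by the
#' number of peaks, so the profile sums to the (multi-assignment-weighted)
#' fraction of peaks assigned.
#'
#' @param peaks peak data.frame.
#' @param genes gene data.frame.
#' @param links link data.frame from \code{\link{assign_peaks_to_genes}}.
#' @param bins number of equal bins over the axis (default 50).
#' @param config the \code{\link{annotation_config}} used for the links.
#' @return list with bin_edges (normalized axis), density, counts, n_links.
#' @export
metagene_profile <- function(peaks, genes, links, bins = 50L,
                             config = annotation_config()) {
  edges <- seq(-1, 2, length.out = bins + 1L)
  if (nrow(links) == 0L) {
    warning("no peak-gene links: empty metagene profile")
    return(list(bin_edges = edges, density = rep(0, bins),
                counts = rep(0L, bins), n_links = 0L, n_peaks = nrow(peaks)))
  }
  anchor_all <- peak_anchor(peaks, config$anchor)
  p <- match(links$peak_id, peaks$id)
  g <- match(links$gene_id, genes$id)
  x <- metagene_coords(anchor_all[p], g, genes, config)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > bins] <- bins
  counts <- tabulate(idx, nbins = bins)
  list(bin_edges = edges, density = counts / nrow(peaks),
       counts = counts, n_links = nrow(links), n_peaks = nrow(peaks))
}

#' Random placements of a length-matched peak multiset
#'
#' For each of \code{n_sets} randomizations, every observed peak length is
#' placed uniformly: the chromosome is chosen with probability proportional
#' to the number of start positions where the peak fits, and the start
#' uniformly among them.  Every set therefore reproduces the observed
#' length multiset exactly.
#'
#' @param lens integer vector of observed peak lengths.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param n_sets number of random sets.
#' @param seed RNG seed.
#' @return data.frame with columns set, chrom, start, len.
#' @export
random_peak_placements <- function(lens, chrom_sizes, n_sets, seed = 1L) {
  chroms <- names(chrom_sizes)
  n_peaks <- length(lens)
  set.seed(seed)
  chrom_idx <- matrix(0L, nrow = n_peaks, ncol = n_sets)
  for (i in seq_len(n_peaks)) {
    w <- pmax(chrom_sizes - lens[i] + 1L, 0L)
    if (sum(w) == 0) stop("peak of length ", lens[i],
                          " is longer than every chromosome")
    chrom_idx[i, ] <- sample.int(length(chroms), n_sets, replace = TRUE,
                                 prob = w)
  }
  span <- matrix(chrom_sizes[chrom_idx] - rep(lens, n_sets) + 1L,
                 nrow = n_peaks)
  starts <- matrix(floor(stats::runif(n_peaks * n_sets) * span),
                   nrow = n_peaks)
  data.frame(set = rep(seq_len(n_sets), each = n_peaks),
             chrom = chroms[as.vector(chrom_idx)],
             start = as.integer(as.vector(starts)),
             len = rep(lens, n_sets), stringsAsFactors = FALSE)
}

#' Null envelope from randomized length-matched peak sets
#'
#' Each random set reproduces exactly the observed multiset of peak lengths,
#' placed uniformly: for every peak the chromosome is chosen with
#' probability proportional to the number of positions where it fits, and
#' the start uniformly among those positions.  Each set is annotated and
#' profiled exactly like the observed peaks; per-bin means and 2.5/97.5
#' percentiles across sets form the envelope.
#'
#' @param peaks observed peak data.frame (supplies the length multiset).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param genes gene data.frame.
#' @param config an \code{\link{annotation_config}}.
#' @param n_sets number of random sets (default 1000).
#' @param seed RNG seed; the envelope is deterministic given it.
#' @param bins number of metagene bins.
#' @return list with bin_edges, mean, lo95, hi95, n_sets, seed.
#' @export
#' @importFrom stats quantile runif
random_peak_null <- function(peaks, chrom_sizes, genes,
                             config = annotation_config(),
                             n_sets = 1000L, seed = 1L, bins = 50L) {
  lens <- peaks$end - peaks$start
  placeable <- vapply(lens, function(l) sum(pmax(chrom_sizes - l + 1L, 0L)), 0)
  if (any(placeable == 0)) {
    stop("a peak is longer than every chromosome; cannot randomize")
  }
  n_peaks <- length(lens)
  chroms <- names(chrom_sizes)
  placements <- random_peak_placements(lens, chrom_sizes, n_sets, seed)
  anchors <- placements$start + placements$len %/% 2L
  set_id <- placements$set
  chrom_vec <- placements$chrom

  plus <- genes$strand == "+"
  tss <- gene_tss(genes)
  tes <- gene_tes(genes)
  lo <- ifelse(plus, tss - config$upstream_window, tes - config$downstream_window)
  hi <- ifelse(plus, tes + config$downstream_window, tss + config$upstream_window)
  edges <- seq(-1, 2, length.out = bins + 1L)
  counts <- matrix(0L, nrow = n_sets, ncol = bins)
  n_links <- integer(n_sets)
  anchor_vec <- anchors
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    ai <- which(chrom_vec == ch)
    if (!length(gi) || !length(ai)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(anchor_vec[ai], anchor_vec[ai]),
      IRanges::IRanges(lo[gi], hi[gi]))
    if (!length(ov)) next
    a <- ai[S4Vectors_from(ov)]
    g <- gi[S4Vectors_to(ov)]
    x <- metagene_coords(anchor_vec[a], g, genes, config)
    idx <- findInterval(x, edges, rightmost.closed = TRUE)
    idx[idx < 1L] <- 1L
    idx[idx > bins] <- bins
    s <- set_id[a]
    flat <- tabulate((s - 1L) * bins + idx, nbins = n_sets * bins)
    counts <- counts + matrix(flat, nrow = n_sets, ncol = bins, byrow = TRUE)
    tl <- tabulate(s, nbins = n_sets)
    n_links <- n_links + tl
  }
  dens <- counts / n_peaks
  list(bin_edges = edges,
       mean = colMeans(dens),
       lo95 = apply(dens, 2, stats::quantile, probs = 0.025, names = FALSE),
       hi95 = apply(dens, 2, stats::quantile, probs = 0.975, names = FALSE),
       n_sets = n_sets, seed = seed)
}
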