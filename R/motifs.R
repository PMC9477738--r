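# Consensus-motif scanning and motif-architecture statistics: per-peak
# counts, consecutive-motif spacing, background promoter spacing, and
# central positional enrichment within peaks.

#' Define a consensus motif
#'
#' Motifs are exact IUPAC consensus strings, scanned on both strands.
#' Palindromic motifs (equal to their IUPAC reverse complement, like the
#' G-box CACGTG) are reported once, on the forward strand, so they are never
#' double-counted.
#'
#' @param name motif label.
#' @param consensus IUPAC consensus string.
#' @return list with name, consensus, length, palindromic flag.
#' @examples
#' motif_spec("gbox", "CACGTG")$palindromic  # TRUE
#' @export
motif_spec <- function(name, consensus) {
  consensus <- toupper(consensus)
  assert_iupac(consensus)
  list(name = name, consensus = consensus,
       length = nchar(consensus),
       palindromic = identical(consensus, revcomp_iupac(consensus)))
}

#' Built-in motif set
#'
#' The G-box (CACGTG) bound by bHLH factors, the strict 5-mer DOF core
#' (AAAAG), and the degenerate DOF consensus ([T/A]AAAG, IUPAC WAAAG).
#'
#' @return named list of motif specs.
#' @export
builtin_motifs <- function() {
  list(gbox = motif_spec("gbox", "CACGTG"),
       dof = motif_spec("dof", "AAAAG"),
       dof_degenerate = motif_spec("dof_degenerate", "WAAAG"))
}

greedy_nonoverlapping <- function(offsets, motif_len) {
  keep <- logical(length(offsets))
  last_end <- -1L
  for (i in seq_along(offsets)) {
    if (offsets[i] > last_end) {
      keep[i] <- TRUE
      last_end <- offsets[i] + motif_len - 1L
    }
  }
  keep
}

#' Scan one sequence for a consensus motif
#'
#' Exact IUPAC matching on both strands.  Minus-strand matches are reported
#' at their forward-strand start offset (0-based).  N in the subject never
#' matches.  With \code{count_policy = "nonoverlapping"} a greedy
#' left-to-right subset is kept per strand.
#'
#' @param seq a single DNA sequence over A/C/G/T/N (case-insensitive).
#' @param spec a \code{\link{motif_spec}}.
#' @param count_policy "all" (default) or "nonoverlapping".
#' @return data.frame with columns offset (0-based), strand.
#' @export
#' @importFrom Biostrings matchPattern
scan_motif <- function(seq, spec, count_policy = c("all", "nonoverlapping")) {
  count_policy <- match.arg(count_policy)
  seq <- toupper(seq)
  hits <- scan_regions(stats::setNames(seq, "r"), spec,
                       count_policy = count_policy)
  hits$region_id <- NULL
  hits
}

#' Scan a set of region sequences for a consensus motif
#'
#' Vectorized scan over named sequences (e.g. peak sequences); offsets are
#' 0-based within each region.
#'
#' @param seqs named character vector of sequences.
#' @param spec a \code{\link{motif_spec}}.
#' @param count_policy "all" or "nonoverlapping".
#' @return data.frame with columns region_id, motif_name, offset, strand.
#' @export
#' @importFrom Biostrings DNAStringSet vmatchPattern
scan_regions <- function(seqs, spec, count_policy = c("all", "nonoverlapping")) {
  count_policy <- match.arg(count_policy)
  stopifnot(!is.null(names(seqs)))
  seqs <- toupper(seqs)
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(chars, c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("sequence contains non-ACGTN letter(s): ",
                        paste(bad, collapse = ", "))
  subj <- Biostrings::DNAStringSet(seqs)
  one_strand <- function(pattern, strand) {
    mi <- Biostrings::vmatchPattern(pattern, subj, fixed = "subject")
    starts <- IRanges::start(mi)
    n <- lengths(starts)
    if (sum(n) == 0L) {
      return(data.frame(region_id = character(), offset = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    }
    data.frame(region_id = rep(names(seqs), n),
               offset = unlist(starts, use.names = FALSE) - 1L,
               strand = strand, stringsAsFactors = FALSE)
  }
  out <- one_strand(spec$consensus, "+")
  if (!spec$palindromic) {
    out <- rbind(out, one_strand(revcomp_iupac(spec$consensus), "-"))
  }
  out <- out[order(match(out$region_id, names(seqs)), out$offset,
                   out$strand), , drop = FALSE]
  if (count_policy == "nonoverlapping" && nrow(out)) {
    keep <- unlist(lapply(split(seq_len(nrow(out)),
                                list(out$region_id, out$strand), drop = TRUE),
                          function(i) {
                            i[greedy_nonoverlapping(out$offset[i], spec$length)]
                          }), use.names = FALSE)
    out <- out[sort(keep), , drop = FALSE]
  }
  out$motif_name <- if (nrow(out)) spec$name else character(0)
  rownames(out) <- NULL
  out[, c("region_id", "motif_name", "offset", "strand")]
}

# Extract region sequences (0-based half-open coordinates) from a genome.
region_sequences <- function(genome, regions) {
  miss <- setdiff(unique(regions$chrom), names(genome))
  if (length(miss)) stop("chromosome(s) absent from genome: ",
                         paste(miss, collapse = ", "))
  out <- substring(genome[regions$chrom], regions$start + 1L, regions$end)
  names(out) <- regions$id
  out
}

#' Scan peaks for a motif against a genome
#' @param genome named character vector of chromosome sequences.
#' @param peaks peak data.frame.
#' @param spec a \code{\link{motif_spec}}.
#' @param count_policy "all" or "nonoverlapping".
#' @return hit data.frame as from \code{\link{scan_regions}}.
#' @export
scan_peaks <- function(genome, peaks, spec,
                       count_policy = c("all", "nonoverlapping")) {
  scan_regions(region_sequences(genome, peaks), spec,
               count_policy = match.arg(count_policy))
}

#' Per-peak motif counts
#'
#' Peaks with zero hits are included at count 0; the count vector always sums
#' its frequencies back to the number of peaks.
#'
#' @param hits hit data.frame (one motif).
#' @param peaks peak data.frame.
#' @return named integer vector of hit counts, one entry per peak.
#' @export
motif_counts_per_peak <- function(hits, peaks) {
  unknown <- setdiff(unique(hits$region_id), peaks$id)
  if (length(unknown)) stop("hit references unknown peak: ", unknown[1])
  counts <- stats::setNames(integer(nrow(peaks)), peaks$id)
  if (nrow(hits)) {
    tab <- table(hits$region_id)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Frequency table of per-peak motif counts
#' @param counts named vector from \code{\link{motif_counts_per_peak}}.
#' @return data.frame with columns k (motif count) and n_peaks.
#' @export
count_frequency <- function(counts) {
  tab <- table(factor(counts, levels = 0:max(c(counts, 0L))))
  data.frame(k = as.integer(names(tab)), n_peaks = as.integer(tab))
}

#' Consecutive-motif spacing distribution
#'
#' Within each region, hits of one motif are sorted by forward-strand offset
#' (match strand ignored) and successive start-to-start differences are
#' pooled across regions.  Regions with fewer than two hits contribute
#' nothing.  The mode estimate is the center of the maximal histogram bin
#' (ties broken toward the smallest distance).
#'
#' @param hits hit data.frame for one motif.
#' @param bin_width histogram bin width in bp (default 5).
#' @return list with distances, histogram (bin_lo, bin_hi, count),
#'   bin_width, mode_estimate (NA when no distances).
#' @export
spacing_distances <- function(hits, bin_width = 5L) {
  dists <- integer(0)
  if (nrow(hits)) {
    by_region <- split(hits$offset, hits$region_id)
    dists <- unlist(lapply(by_region, function(o) {
      if (length(o) < 2L) return(integer(0))
      diff(sort(o))
    }), use.names = FALSE)
  }
  if (length(dists) == 0L) {
    return(list(distances = integer(0),
                histogram = data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                                       count = integer(0)),
                bin_width = bin_width, mode_estimate = NA_real_))
  }
  edges <- seq(0, ceiling(max(dists) / bin_width) * bin_width, by = bin_width)
  if (length(edges) < 2L) edges <- c(0, bin_width)
  idx <- findInterval(dists, edges, rightmost.closed = TRUE)
  cnt <- tabulate(idx, nbins = length(edges) - 1L)
  hist <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                     count = cnt)
  best <- which.max(cnt)
  list(distances = dists, histogram = hist, bin_width = bin_width,
       mode_estimate = (hist$bin_lo[best] + hist$bin_hi[best]) / 2)
}

#' Promoter-background spacing distribution
#'
#' Scans the promoters (a window 5' of the TSS, in gene orientation) of all
#' genes NOT in the target set and computes the spacing distribution there.
#' This is the background against which peak spacing modes are judged.
#'
#' @param genes gene data.frame.
#' @param target_gene_ids ids of target genes to exclude.
#' @param genome named character vector of chromosome sequences.
#' @param spec a \code{\link{motif_spec}}.
#' @param promoter_window promoter length in bp 5' of the TSS (default 1000).
#' @param bin_width spacing histogram bin width.
#' @return a spacing distribution as from \code{\link{spacing_distances}}.
#' @export
background_spacing <- function(genes, target_gene_ids, genome, spec,
                               promoter_window = 1000L, bin_width = 5L) {
  bg <- genes[!genes$id %in% target_gene_ids, , drop = FALSE]
  if (nrow(bg) == 0L) stop("no non-target genes: background set is empty")
  plus <- bg$strand == "+"
  start <- ifelse(plus, bg$start - promoter_window, bg$end)
  end <- ifelse(plus, bg$start, bg$end + promoter_window)
  clen <- nchar(genome)[bg$chrom]
  start <- pmax(start, 0L)
  end <- pmin(end, clen)
  keep <- start < end
  proms <- data.frame(id = paste0("prom_", bg$id[keep]),
                      chrom = bg$chrom[keep],
                      start = as.integer(start[keep]),
                      end = as.integer(end[keep]),
                      stringsAsFactors = FALSE)
  hits <- scan_regions(region_sequences(genome, proms), spec)
  spacing_distances(hits, bin_width = bin_width)
}

#' Central enrichment of motif hits within peaks
#'
#' For each candidate halfwidth w, counts hits whose match midpoint lies
#' within w of the peak midpoint, compares against the fraction expected
#' under uniform placement (mean over peaks of min(2w, placeable span) /
#' placeable span), and reports a one-sided binomial upper-tail p value,
#' Bonferroni-adjusted over the candidate windows.  The smallest adjusted p
#' is flagged as best.
#'
#' @param hits hit data.frame for one motif.
#' @param peaks peak data.frame.
#' @param spec the scanned \code{\link{motif_spec}}.
#' @param candidate_halfwidths integer vector of window halfwidths in bp.
#' @return data.frame with one row per usable window: halfwidth,
#'   hits_in_window, hits_total, expected_fraction, p, p_adj, best.
#' @export
#' @importFrom stats pbinom
central_enrichment <- function(hits, peaks, spec,
                               candidate_halfwidths = c(25L, 50L, 100L, 250L)) {
  len <- stats::setNames(peaks$end - peaks$start, peaks$id)
  span <- pmax(len - spec$length + 1L, 1L)
  total <- nrow(hits)
  rows <- lapply(candidate_halfwidths, function(w) {
    if (all(2 * w >= span)) {
      warning("central window halfwidth ", w,
              " exceeds every peak half-span; skipped")
      return(NULL)
    }
    expected <- mean(pmin(2 * w, span) / span)
    if (total == 0L) {
      return(data.frame(halfwidth = w, hits_in_window = 0L, hits_total = 0L,
                        expected_fraction = expected, p = 1))
    }
    peak_len <- len[hits$region_id]
    centered <- abs(hits$offset + spec$length / 2 - peak_len / 2) <= w
    k <- sum(centered)
    p <- stats::pbinom(k - 1L, total, expected, lower.tail = FALSE)
    data.frame(halfwidth = w, hits_in_window = k, hits_total = total,
               expected_fraction = expected, p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop("no usable candidate window for central enrichment")
  }
  out$p_adj <- pmin(out$p * nrow(out), 1)
  out$best <- seq_len(nrow(out)) == which.min(out$p_adj)
  rownames(out) <- NULL
  out
}
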