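# Independent oracles and small fixture builders used across the suite.

# Brute-force motif scan by regular-expression enumeration over both
# strands: deliberately independent of the Biostrings-based scanner.
iupac_to_regex <- function(consensus) {
  classes <- c(A = "A", C = "C", G = "G", T = "T",
               R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
               K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
               H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(classes[strsplit(toupper(consensus), "")[[1]]], collapse = "")
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# all overlapping match offsets (0-based) of a regex in a sequence
regex_offsets <- function(seq, rx) {
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

oracle_scan <- function(seq, consensus) {
  seq <- toupper(seq)
  consensus <- toupper(consensus)
  palindromic <- identical(consensus, oracle_revcomp(consensus))
  fwd <- regex_offsets(seq, iupac_to_regex(consensus))
  out <- data.frame(offset = fwd, strand = rep("+", length(fwd)),
                    stringsAsFactors = FALSE)
  if (!palindromic) {
    rev <- regex_offsets(seq, iupac_to_regex(oracle_revcomp(consensus)))
    out <- rbind(out, data.frame(offset = rev,
                                 strand = rep("-", length(rev)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

random_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# exhaustive hypergeometric upper tail by enumerating every |A|-subset of
# the universe {1..N} with successes {1..b}
oracle_hyper_upper <- function(N, a, b, k) {
  if (a == 0L) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, a)
  overlap <- colSums(subsets <= b)
  mean(overlap >= k)
}

# tiny deterministic fixture: two genes on opposite strands plus peaks
tiny_genes <- function() {
  data.frame(id = c("gA", "gB"), chrom = c("chr1", "chr1"),
             start = c(5000L, 20000L), end = c(7000L, 22000L),
             strand = c("+", "-"), stringsAsFactors = FALSE)
}

make_peaks <- function(centers, chrom = "chr1", len = 200L,
                       ids = NULL, score = 1) {
  n <- length(centers)
  data.frame(id = ids %||% paste0("p", seq_len(n)), chrom = chrom,
             start = as.integer(centers - len %/% 2L),
             end = as.integer(centers + len - len %/% 2L),
             strand = ".", score = score, summit_offset = NA_integer_,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
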