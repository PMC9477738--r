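# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom Biostrings DNAString reverseComplement
revcomp_iupac <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

assert_iupac <- function(consensus) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  if (length(chars) == 0L) stop("motif consensus must be non-empty")
  bad <- setdiff(chars, IUPAC_CODES)
  if (length(bad)) {
    stop("invalid IUPAC code(s) in consensus: ", paste(unique(bad), collapse = ", "))
  }
  invisible(TRUE)
}

# Peak/gene tables carry 0-based half-open coordinates throughout the package;
# GFF3 input is converted at the boundary.
validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!nzchar(df$chrom))) stop(what, ": empty chromosome name")
  if (any(df$start < 0L)) stop(what, ": negative start coordinate")
  if (any(df$start >= df$end)) stop(what, ": start >= end")
  invisible(df)
}

# Anchor position of each peak: the center by default, the summit when
# requested and recorded.  0-based genomic position.
peak_anchor <- function(peaks, anchor = c("center", "summit")) {
  anchor <- match.arg(anchor)
  center <- peaks$start + (peaks$end - peaks$start) %/% 2L
  if (anchor == "summit" && "summit_offset" %in% names(peaks)) {
    s <- peaks$start + peaks$summit_offset
    ifelse(is.na(s), center, s)
  } else {
    center
  }
}

# Deterministic sub-seed for a named simulation stage, derived from the master
# seed.  Offsets are fixed so each stage is reproducible in isolation and the
# composed pipeline draws are independent streams.
stage_seed <- function(seed, stage) {
  offsets <- c(genome = 0L, peaks = 1L, motifs = 2L, counts = 3L,
               degs = 4L, null = 5L)
  if (!stage %in% names(offsets)) stop("unknown rng stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}
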