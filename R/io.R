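# Readers and writers for the plain-text formats the pipeline touches.
# All interval records are normalized to 0-based half-open coordinates on
# read; GFF3 (1-based closed) is converted at this boundary and nowhere else.
# Chromosome names are taken verbatim: no "chr" normalization is attempted,
# so peak and gene files must share a chromosome namespace.

parse_int <- function(x, path, lineno, field) {
  v <- suppressWarnings(as.integer(x))
  bad <- is.na(v) | (x != as.character(v))
  if (any(bad)) {
    stop(sprintf("%s: line %d: field '%s' is not an integer: '%s'",
                 path, lineno[bad][1], field, x[bad][1]), call. = FALSE)
  }
  v
}

#' Read peaks from a BED6 or narrowPeak file
#'
#' BED half-open 0-based coordinates are preserved verbatim.  For the
#' narrowPeak dialect, column 7 (signalValue) becomes the peak score and
#' column 10 the summit offset (-1 encodes absent).  For BED6 the score is
#' column 5.  Peaks named "." get auto-generated ids \code{peak_<n>}.
#'
#' @param path path to a tab-separated BED6 or 10-column narrowPeak file.
#' @param dialect one of "bed6", "narrowPeak".
#' @return data.frame with columns id, chrom, start, end, strand, score,
#'   summit_offset (NA when absent).
#' @export
read_peaks <- function(path, dialect = c("bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      summit_offset = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (dialect == "narrowPeak") 10L else 3L
  if (any(nf < need)) {
    stop(sprintf("%s: line %d: expected >= %d tab-separated fields, got %d",
                 path, which(nf < need)[1], need, min(nf)), call. = FALSE)
  }
  lineno <- seq_along(lines)
  col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  chrom <- col(1)
  start <- parse_int(col(2), path, lineno, "start")
  end <- parse_int(col(3), path, lineno, "end")
  bad <- start >= end
  if (any(bad)) {
    stop(sprintf("%s: line %d: start >= end (%d >= %d)",
                 path, lineno[bad][1], start[bad][1], end[bad][1]), call. = FALSE)
  }
  if (any(start < 0L)) {
    stop(sprintf("%s: line %d: negative start", path, lineno[start < 0L][1]),
         call. = FALSE)
  }
  name <- col(4)
  id <- ifelse(is.na(name) | name == "." | name == "",
               paste0("peak_", lineno), name)
  strand <- col(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  if (dialect == "narrowPeak") {
    score <- suppressWarnings(as.numeric(col(7)))
    summit <- parse_int(col(10), path, lineno, "summit")
    summit[summit < 0L] <- NA_integer_
    in_range <- is.na(summit) | summit < (end - start)
    if (any(!in_range)) {
      stop(sprintf("%s: line %d: summit offset outside peak",
                   path, lineno[!in_range][1]), call. = FALSE)
    }
  } else {
    score <- suppressWarnings(as.numeric(col(5)))
    summit <- rep(NA_integer_, length(lines))
  }
  score[is.na(score)] <- 0
  if (any(score < 0)) {
    stop(sprintf("%s: line %d: negative score", path, lineno[score < 0][1]),
         call. = FALSE)
  }
  data.frame(id = id, chrom = chrom, start = start, end = end,
             strand = strand, score = score, summit_offset = summit,
             stringsAsFactors = FALSE)
}

#' Write peaks as BED6 (or narrowPeak)
#'
#' @param peaks peak data.frame as returned by \code{\link{read_peaks}}.
#' @param path output path.
#' @param dialect output dialect.
#' @export
write_peaks <- function(peaks, path, dialect = c("bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed6") {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                     peaks$chrom, peaks$start, peaks$end, peaks$id,
                     format(peaks$score, trim = TRUE, scientific = FALSE),
                     peaks$strand)
  } else {
    summit <- ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset)
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t-1\t-1\t%d",
                     peaks$chrom, peaks$start, peaks$end, peaks$id,
                     peaks$strand,
                     format(peaks$score, trim = TRUE, scientific = FALSE),
                     summit)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Only features of type "gene" are read; 1-based closed GFF coordinates are
#' converted to the package-internal 0-based half-open convention
#' (start - 1, end).  The TSS is the first transcribed base: position
#' \code{start} on "+" genes and \code{end - 1} on "-" genes.
#'
#' @param path path to a GFF3 file whose gene features carry an ID attribute.
#' @return data.frame with columns id, chrom, start, end, strand.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(lines) && any(nf < 9L)) {
    stop(sprintf("%s: line %d: expected 9 GFF3 fields",
                 path, lineno[nf < 9L][1]), call. = FALSE)
  }
  type <- vapply(fields, `[`, "", 3L)
  sel <- type == "gene"
  fields <- fields[sel]
  lineno <- lineno[sel]
  if (length(fields) == 0L) {
    return(data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start1 <- parse_int(vapply(fields, `[`, "", 4L), path, lineno, "start")
  end1 <- parse_int(vapply(fields, `[`, "", 5L), path, lineno, "end")
  strand <- vapply(fields, `[`, "", 7L)
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop(sprintf("%s: line %d: gene without usable strand ('%s')",
                 path, lineno[bad][1], strand[bad][1]), call. = FALSE)
  }
  attrs <- vapply(fields, `[`, "", 9L)
  m <- regmatches(attrs, regexpr("(^|;)ID=[^;]+", attrs))
  has_id <- grepl("(^|;)ID=", attrs)
  if (any(!has_id)) {
    stop(sprintf("%s: line %d: gene feature without ID attribute",
                 path, lineno[!has_id][1]), call. = FALSE)
  }
  id <- sub("^;?ID=", "", m)
  df <- data.frame(id = id, chrom = chrom, start = start1 - 1L, end = end1,
                   strand = strand, stringsAsFactors = FALSE)
  validate_intervals(df, "gene")
  if (anyDuplicated(df$id)) stop(path, ": duplicate gene ID")
  df
}

#' Write gene models as GFF3
#' @param genes gene data.frame (0-based half-open coordinates).
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tcobind\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end,
                     genes$strand, genes$id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read so motif scanning is case-insensitive by
#' construction.  Duplicate headers are an error.
#'
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
#' @importFrom Biostrings readDNAStringSet
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop(path, ": duplicate FASTA header: ", nm[duplicated(nm)][1])
  }
  out <- toupper(as.character(ss))
  names(out) <- nm
  out
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
#' @importFrom Biostrings DNAStringSet writeXStringSet
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a per-region count matrix from TSV
#'
#' The first column holds region (peak or gene) ids; remaining columns are
#' samples.  Counts must be non-negative integers and ids unique.
#'
#' @param path TSV path with a header row.
#' @return integer matrix with region ids as rownames, samples as colnames.
#' @export
#' @importFrom utils read.delim write.table
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(path, ": count matrix needs an id column plus samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop(path, ": duplicate row id: ", ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  if (anyNA(m)) stop(path, ": non-numeric count value")
  if (any(m < 0)) stop(path, ": negative count value")
  if (any(m != floor(m))) stop(path, ": non-integral count value")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a count matrix as TSV
#' @param m matrix with rownames and colnames.
#' @param path output path.
#' @param id_col name of the id column.
#' @export
write_count_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table from TSV
#'
#' Expects columns gene_id, log2fc, padj (header names matched
#' case-insensitively; the first three columns are used in that order when
#' names do not match).
#'
#' @param path TSV path with a header row.
#' @return data.frame with columns gene_id, log2fc, padj.
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  pick <- function(cands, fallback) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) fallback else i
  }
  gi <- pick(c("gene_id", "gene", "id"), 1L)
  fi <- pick(c("log2fc", "log2foldchange", "lfc"), 2L)
  pi <- pick(c("padj", "adj_p", "fdr", "qvalue"), 3L)
  out <- data.frame(gene_id = as.character(df[[gi]]),
                    log2fc = as.numeric(df[[fi]]),
                    padj = as.numeric(df[[pi]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$log2fc) || anyNA(out$padj)) {
    stop(path, ": non-numeric log2fc or padj")
  }
  if (any(out$padj < 0 | out$padj > 1)) {
    stop(path, ": padj outside [0, 1]")
  }
  if (anyDuplicated(out$gene_id)) {
    stop(path, ": duplicate gene_id: ", out$gene_id[duplicated(out$gene_id)][1])
  }
  out
}

#' Write a differential-expression table as TSV
#' @param deg data.frame with gene_id, log2fc, padj.
#' @param path output path.
#' @export
write_deg_table <- function(deg, path) {
  utils::write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
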