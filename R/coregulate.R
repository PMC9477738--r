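# DEG filtering, gene-set overlap tests, direction-consistency
# classification, and the evidence-layer intersection that defines the
# cooperatively regulated gene set.

#' DEG filter configuration
#'
#' The fold-change boundary is inclusive (|log2fc| >= log2(threshold)), the
#' adjusted-p boundary strict (padj < threshold).
#'
#' @param fold_change_threshold linear fold-change threshold (default 1.5).
#' @param padj_threshold adjusted-p threshold (default 0.05).
#' @return list of settings.
#' @export
deg_filter_config <- function(fold_change_threshold = 1.5,
                              padj_threshold = 0.05) {
  stopifnot(fold_change_threshold > 0, padj_threshold > 0)
  list(fold_change_threshold = fold_change_threshold,
       padj_threshold = padj_threshold)
}

#' Filter a DEG table to significant genes with directions
#'
#' @param table data.frame with gene_id, log2fc, padj.
#' @param config a \code{\link{deg_filter_config}}.
#' @return data.frame with gene_id, log2fc, padj, direction (+1/-1).
#' @export
filter_degs <- function(table, config = deg_filter_config()) {
  keep <- abs(table$log2fc) >= log2(config$fold_change_threshold) &
    table$padj < config$padj_threshold
  out <- table[keep, , drop = FALSE]
  out$direction <- sign(out$log2fc)
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail probability P(X >= n_overlap) of drawing at least the observed
#' overlap when |A| genes are drawn without replacement from a universe of
#' which |B| are "successes".
#'
#' @param setA,setB character vectors of gene ids, subsets of universe.
#' @param universe character vector of all gene ids considered.
#' @return list with n_universe, n_setA, n_setB, n_overlap, p.
#' @export
#' @importFrom stats phyper
overlap_test <- function(setA, setB, universe) {
  setA <- unique(setA)
  setB <- unique(setB)
  universe <- unique(universe)
  if (length(setdiff(setA, universe)) || length(setdiff(setB, universe))) {
    stop("set member outside universe")
  }
  k <- length(intersect(setA, setB))
  N <- length(universe)
  p <- stats::phyper(k - 1L, length(setB), N - length(setB), length(setA),
                     lower.tail = FALSE)
  list(n_universe = N, n_setA = length(setA), n_setB = length(setB),
       n_overlap = k, p = p)
}

#' Direction consistency of shared DEGs
#'
#' Computed on the intersection of the two filtered DEG sets: how many shared
#' genes move the same way in both genotypes, and what fraction move in
#' opposite directions.
#'
#' @param degA,degB filtered DEG data.frames from \code{\link{filter_degs}}.
#' @return list with n_shared, n_same_up, n_same_down, n_opposite,
#'   fraction_opposite (NA when the intersection is empty).
#' @export
direction_consistency <- function(degA, degB) {
  shared <- intersect(degA$gene_id, degB$gene_id)
  if (length(shared) == 0L) {
    return(list(n_shared = 0L, n_same_up = 0L, n_same_down = 0L,
                n_opposite = 0L, fraction_opposite = NA_real_))
  }
  da <- degA$direction[match(shared, degA$gene_id)]
  db <- degB$direction[match(shared, degB$gene_id)]
  same_up <- sum(da > 0 & db > 0)
  same_down <- sum(da < 0 & db < 0)
  opp <- sum(da * db < 0)
  list(n_shared = length(shared), n_same_up = same_up,
       n_same_down = same_down, n_opposite = opp,
       fraction_opposite = opp / length(shared))
}

#' Cooperative gene set: four-way evidence intersection
#'
#' A gene is cooperative when it is (1) differentially expressed in both
#' genotypes, (2) bound by factor A, (3) bound by factor B, and (4) shows
#' significantly reduced binding of factor A when factor B is absent
#' (derived upstream from differential-binding peaks with significant
#' negative log2fc, mapped through peak-gene links).
#'
#' @param shared_degs gene ids differentially expressed in both genotypes.
#' @param bound_by_A,bound_by_B gene ids bound by each factor.
#' @param reduced_binding_genes gene ids with significantly reduced binding.
#' @param tissue optional tissue label carried into the result.
#' @return list with tissue, gene_ids (sorted), provenance (data.frame of
#'   per-layer membership, all TRUE by construction).
#' @export
cooperative_genes <- function(shared_degs, bound_by_A, bound_by_B,
                              reduced_binding_genes, tissue = NA_character_) {
  ids <- Reduce(intersect, list(unique(shared_degs), unique(bound_by_A),
                                unique(bound_by_B),
                                unique(reduced_binding_genes)))
  ids <- sort(ids)
  provenance <- data.frame(gene_id = ids,
                           shared_deg = ids %in% shared_degs,
                           bound_by_A = ids %in% bound_by_A,
                           bound_by_B = ids %in% bound_by_B,
                           reduced_binding = ids %in% reduced_binding_genes,
                           stringsAsFactors = FALSE)
  list(tissue = tissue, gene_ids = ids, provenance = provenance)
}

#' Row-wise z-score normalization
#'
#' Each row is centered and scaled to population standard deviation 1
#' (divisor n, not n - 1, as used for expression heatmaps).  Constant rows
#' become all zeros with a warning.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  if (ncol(m) < 2L) stop("need >= 2 columns per row")
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  const <- sdev == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) set to zero")
    sdev[const] <- 1
  }
  out <- (m - mu) / sdev
  out[const, ] <- 0
  out
}
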