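# Binding-strength stratification by motif count (Kruskal-Wallis, pairwise
# Wilcoxon rank-sum with BH adjustment, compact letter display) and
# differential peak occupancy between genotypes from replicated counts.
#
# The rank tests are written out explicitly (with tie corrections) so their
# algebra is inspectable; stats::kruskal.test / stats::wilcox.test are used
# as independent cross-checks in the test suite, never called here.

#' Stratify peak scores by motif count
#'
#' Groups are keyed "0", "1", ..., with counts at or above \code{max_group}
#' pooled into one ">=max_group" group.  Empty groups are dropped with a
#' warning.
#'
#' @param peaks peak data.frame with a score column.
#' @param counts_per_peak named vector from
#'   \code{\link{motif_counts_per_peak}}.
#' @param max_group pooling threshold (default 3).
#' @return named list of score vectors.
#' @export
stratify_by_motif_count <- function(peaks, counts_per_peak, max_group = 3L) {
  k <- counts_per_peak[peaks$id]
  if (anyNA(k)) stop("peak without a motif count")
  lab <- ifelse(k >= max_group, paste0(">=", max_group), as.character(k))
  levels <- c(as.character(seq(0L, max_group - 1L)), paste0(">=", max_group))
  groups <- split(peaks$score, factor(lab, levels = levels))
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    warning("dropping empty motif-count group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  groups
}

#' Kruskal-Wallis rank test
#'
#' H is computed from the rank sums with the standard tie correction and
#' referred to a chi-square distribution with (groups - 1) degrees of
#' freedom.
#'
#' @param groups named list of numeric vectors (>= 2 non-empty groups,
#'   total n >= 3).
#' @return list with H, p, df.
#' @export
#' @importFrom stats pchisq
kruskal_wallis <- function(groups) {
  groups <- groups[lengths(groups) > 0L]
  g <- length(groups)
  if (g < 2L) stop("Kruskal-Wallis needs at least 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (n < 3L) stop("Kruskal-Wallis needs total n >= 3")
  r <- rank(x)
  grp <- rep(seq_len(g), lengths(groups))
  rsum <- tapply(r, grp, sum)
  ni <- lengths(groups)
  H <- 12 / (n * (n + 1)) * sum(rsum^2 / ni) - 3 * (n + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr > 0) H <- H / tie_corr
  list(H = H, p = stats::pchisq(H, df = g - 1L, lower.tail = FALSE),
       df = g - 1L)
}

#' Wilcoxon rank-sum test (normal approximation, tie-corrected)
#'
#' Two-sided; the statistic W is the Mann-Whitney count for x against y
#' (identical to the W of the standard rank-sum test).  No continuity
#' correction is applied.
#'
#' @param x,y numeric vectors.
#' @return list with W, p.
#' @export
#' @importFrom stats pnorm
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group in Wilcoxon test")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  n <- nx + ny
  ties <- table(c(x, y))
  sigma2 <- nx * ny / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(W = W, p = 1))
  z <- (W - nx * ny / 2) / sqrt(sigma2)
  list(W = W, p = min(1, 2 * stats::pnorm(-abs(z))))
}

# Compact letter display by insert-and-absorb: start from one column holding
# every group; for each significantly different pair split every column that
# still contains both members; finally absorb columns that are subsets of
# others.  By construction two groups share a letter iff their pair was
# never split, i.e. iff adjusted p >= alpha.
letter_display <- function(group_names, sig_pairs) {
  absorb <- function(cols) {
    # drop duplicates, then any column that is a subset of a larger one
    cols <- unique(lapply(cols, sort))
    cols <- cols[order(-lengths(cols))]
    kept <- list()
    for (col in cols) {
      if (!any(vapply(kept, function(k) all(col %in% k), FALSE))) {
        kept <- c(kept, list(col))
      }
    }
    kept
  }
  columns <- list(group_names)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$a[k]
    b <- sig_pairs$b[k]
    new_cols <- list()
    for (col in columns) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    columns <- absorb(Filter(length, new_cols))
  }
  # keep letter order aligned with group order
  columns <- columns[order(vapply(columns,
                                  function(c) min(match(c, group_names)), 0))]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- stats::setNames(rep("", length(group_names)), group_names)
  for (i in seq_along(columns)) {
    for (gname in columns[[i]]) {
      out[gname] <- paste0(out[gname], letters_pool[i])
    }
  }
  out
}

#' Pairwise rank-sum tests with compact letter display
#'
#' All unordered group pairs are compared by the two-sided tie-corrected
#' Wilcoxon rank-sum test; p values are adjusted across pairs
#' (Benjamini-Hochberg by default) and letters assigned so that two groups
#' share at least one letter exactly when their adjusted p >= alpha.
#' Kruskal-Wallis results for the same grouping are included.
#'
#' @param groups named list of numeric score vectors.
#' @param alpha significance level for the letter display (default 0.05).
#' @param adjust p-adjustment method passed to \code{stats::p.adjust}.
#' @return list with groups, kw_H, kw_p, pairwise (data.frame a, b, W, p,
#'   p_adj), letters (named character vector).
#' @export
#' @importFrom stats p.adjust
pairwise_letters <- function(groups, alpha = 0.05, adjust = "BH") {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) == 0L)) stop("group of size 0")
  kw <- kruskal_wallis(groups)
  nm <- names(groups)
  pairs <- utils::combn(nm, 2L)
  res <- apply(pairs, 2, function(pr) {
    wt <- wilcoxon_rank_sum(groups[[pr[1]]], groups[[pr[2]]])
    c(W = wt$W, p = wt$p)
  })
  pw <- data.frame(a = pairs[1, ], b = pairs[2, ],
                   W = res["W", ], p = res["p", ],
                   stringsAsFactors = FALSE)
  pw$p_adj <- stats::p.adjust(pw$p, method = adjust)
  letters <- letter_display(nm, pw[pw$p_adj < alpha, c("a", "b"), drop = FALSE])
  list(groups = groups, kw_H = kw$H, kw_p = kw$p,
       pairwise = pw, letters = letters, alpha = alpha)
}

#' Median-of-ratios size factors and normalized counts
#'
#' Size factors are the median across rows of the ratio of each sample's
#' counts to the row geometric mean, using only rows positive in all
#' samples.  If no such row exists, library-size ratios (scaled to
#' geometric mean 1) are used with a warning.
#'
#' @param m integer count matrix (regions x samples, >= 2 samples).
#' @return list with size_factors (named numeric) and normalized (matrix).
#' @export
#' @importFrom stats median
normalize_counts <- function(m) {
  if (ncol(m) < 2L) stop("need at least 2 samples")
  libsize <- colSums(m)
  if (any(libsize == 0)) stop("sample with all-zero counts")
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    warning("no row positive in all samples; falling back to library-size ratios")
    sf <- libsize / exp(mean(log(libsize)))
  } else {
    lm <- log(m[allpos, , drop = FALSE])
    ref <- rowMeans(lm)
    sf <- apply(exp(lm - ref), 2, stats::median)
  }
  names(sf) <- colnames(m)
  list(size_factors = sf,
       normalized = sweep(m, 2, sf, "/"))
}

# Moment-matching fit of a scaled inverse chi-square prior to observed
# per-peak sample variances s2 (each on d residual df): returns prior df d0
# (possibly Inf) and prior variance s02.  This is the standard
# empirical-Bayes squeeze used for small-replicate expression/occupancy
# designs, fitted via the log-variance moments.
fit_variance_prior <- function(s2, d) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2L) {
    s02 <- if (any(ok)) mean(s2[ok]) else 0
    return(list(d0 = Inf, s02 = s02))
  }
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(ebar)))
  }
  # invert trigamma(d0/2) = evar by Newton iteration
  y <- 0.5 + 1 / evar
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / evar) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) < 1e-8) break
  }
  d0 <- 2 * y
  s02 <- exp(ebar + digamma(y) - log(y))
  list(d0 = d0, s02 = s02)
}

#' Differential peak occupancy between two conditions
#'
#' Counts are median-of-ratios normalized, shifted by a 0.5 pseudocount and
#' log2-transformed; each peak is tested by a two-sided t test between
#' conditions and p values are BH-adjusted across peaks.  log2fc is the
#' difference of condition means on the log2 scale (condition2 minus
#' condition1).  With \code{moderate = TRUE} (the default) per-peak pooled
#' variances are shrunk toward an empirical-Bayes prior fitted across peaks
#' and the t reference gains the prior degrees of freedom — at typical
#' replicate numbers (2-4) an unmoderated test has too few degrees of
#' freedom for any peak to clear a BH threshold, however large its fold
#' change.  \code{moderate = FALSE} gives the plain per-peak Welch test.
#' A peak with zero variance and equal means in both conditions gets p = 1.
#'
#' @param m integer count matrix (peaks x samples).
#' @param condition_of named character vector mapping sample to condition
#'   (exactly 2 conditions, >= 2 replicates each).
#' @param fdr_threshold significance threshold on the BH-adjusted p
#'   (default 0.05); significant means fdr <= threshold.
#' @param cond_order optional length-2 character vector fixing which
#'   condition is condition1 (reference) and condition2.
#' @param moderate use empirical-Bayes variance moderation (default TRUE).
#' @return data.frame with peak_id, mean condition columns, log2fc, p, fdr,
#'   significant.
#' @export
#' @importFrom stats pt var
differential_binding <- function(m, condition_of, fdr_threshold = 0.05,
                                 cond_order = NULL, moderate = TRUE) {
  if (is.null(names(condition_of))) {
    stopifnot(length(condition_of) == ncol(m))
    names(condition_of) <- colnames(m)
  }
  condition_of <- condition_of[colnames(m)]
  conds <- cond_order %||% unique(condition_of)
  if (length(conds) != 2L) stop("exactly 2 conditions required")
  i1 <- which(condition_of == conds[1])
  i2 <- which(condition_of == conds[2])
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("need at least 2 replicates per condition")
  }
  norm <- normalize_counts(m)$normalized
  l <- log2(norm + 0.5)
  m1 <- rowMeans(l[, i1, drop = FALSE])
  m2 <- rowMeans(l[, i2, drop = FALSE])
  v1 <- apply(l[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(l[, i2, drop = FALSE], 1, stats::var)
  n1 <- length(i1)
  n2 <- length(i2)
  diff <- m2 - m1
  p <- numeric(nrow(m))
  if (moderate) {
    d <- n1 + n2 - 2L
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    prior <- fit_variance_prior(s2, d)
    if (is.finite(prior$d0)) {
      s2_tilde <- (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
      df_tot <- d + prior$d0
    } else {
      s2_tilde <- rep(prior$s02, length(s2))
      df_tot <- Inf
    }
    se2 <- s2_tilde * (1 / n1 + 1 / n2)
    degenerate <- se2 == 0
    p[degenerate & diff == 0] <- 1
    p[degenerate & diff != 0] <- 0
    ok <- !degenerate
    if (any(ok)) {
      tstat <- diff[ok] / sqrt(se2[ok])
      p[ok] <- if (is.finite(df_tot)) {
        2 * stats::pt(-abs(tstat), df_tot)
      } else {
        2 * stats::pnorm(-abs(tstat))
      }
    }
  } else {
    se2 <- v1 / n1 + v2 / n2
    degenerate <- se2 == 0
    p[degenerate & diff == 0] <- 1
    p[degenerate & diff != 0] <- 0
    ok <- !degenerate
    if (any(ok)) {
      tstat <- diff[ok] / sqrt(se2[ok])
      df <- se2[ok]^2 / (v1[ok]^2 / (n1^2 * (n1 - 1)) +
                           v2[ok]^2 / (n2^2 * (n2 - 1)))
      p[ok] <- 2 * stats::pt(-abs(tstat), df)
    }
  }
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(peak_id = rownames(m),
                    mean1 = rowMeans(norm[, i1, drop = FALSE]),
                    mean2 = rowMeans(norm[, i2, drop = FALSE]),
                    log2fc = diff, p = p, fdr = fdr,
                    significant = fdr <= fdr_threshold,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("mean_", conds)
  rownames(out) <- NULL
  out
}
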