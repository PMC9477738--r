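# Rank tests against hand-derived values and the reference implementations,
# the compact letter display invariant, normalization, and differential
# occupancy.

test_that("motif-count stratification pools and conserves group sizes", {
  peaks <- make_peaks(c(100, 300, 500, 700), score = c(1, 2, 3, 4))
  counts <- stats::setNames(c(0L, 1L, 1L, 5L), peaks$id)
  groups <- stratify_by_motif_count(peaks, counts, max_group = 2L)
  expect_equal(names(groups), c("0", "1", ">=2"))
  expect_equal(lengths(groups), c("0" = 1L, "1" = 2L, ">=2" = 1L))
  expect_equal(sum(lengths(groups)), nrow(peaks))

  same <- stats::setNames(rep(1L, 4), peaks$id)
  expect_warning(g1 <- stratify_by_motif_count(peaks, same, max_group = 2L),
                 "empty")
  expect_equal(length(g1), 1L)
  expect_error(kruskal_wallis(g1), "2 non-empty groups")
})

test_that("Kruskal-Wallis H matches the hand-derived rank formula", {
  res <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  # rank sums 6 and 15: H = 12/42 * (36/3 + 225/3) - 21 = 3.857
  expect_equal(res$H, 12 / 42 * (36 / 3 + 225 / 3) - 21)
  expect_equal(round(res$H, 3), 3.857)
  expect_equal(res$p, stats::pchisq(res$H, 1, lower.tail = FALSE))

  ident <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(ident$H, 0)
  expect_equal(ident$p, 1)
})

test_that("Kruskal-Wallis agrees with the reference implementation", {
  set.seed(21)
  for (i in 1:100) {
    g <- sample(2:4, 1)
    groups <- lapply(seq_len(g), function(j) {
      round(stats::rnorm(sample(3:10, 1)), sample(0:2, 1))
    })
    names(groups) <- paste0("g", seq_len(g))
    mine <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(unlist(groups),
                               rep(seq_len(g), lengths(groups)))
    expect_lt(abs(mine$H - unname(ref$statistic)), 1e-10)
    expect_lt(abs(mine$p - ref$p.value), 1e-10)
  }
})

test_that("Wilcoxon rank-sum agrees with the reference implementation", {
  set.seed(22)
  for (i in 1:100) {
    x <- round(stats::rnorm(sample(4:12, 1)), 1)
    y <- round(stats::rnorm(sample(4:12, 1), 0.5), 1)
    mine <- wilcoxon_rank_sum(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_lt(abs(mine$W - unname(ref$statistic)), 1e-10)
    expect_lt(abs(mine$p - ref$p.value), 1e-10)
  }
})

test_that("letters separate shifted groups and merge exchangeable ones", {
  set.seed(23)
  far <- list(a = stats::rnorm(50, 0, 1), b = stats::rnorm(50, 10, 1))
  res <- pairwise_letters(far)
  expect_equal(unname(res$letters), c("a", "b"))

  merged <- 0
  for (i in 1:20) {
    same <- list(a = stats::rnorm(15), b = stats::rnorm(15),
                 c = stats::rnorm(15))
    r <- pairwise_letters(same)
    if (all(r$letters == r$letters[1])) merged <- merged + 1
  }
  expect_gt(merged, 10)

  expect_error(pairwise_letters(list(a = 1:3)), "at least 2")
  expect_error(pairwise_letters(list(a = 1:3, b = numeric(0))), "size 0")
})

test_that("letter display encodes exactly the adjusted-p relation", {
  set.seed(24)
  for (i in 1:40) {
    k <- sample(2:6, 1)
    nm <- paste0("g", seq_len(k))
    pm <- matrix(1, k, k, dimnames = list(nm, nm))
    pairs <- utils::combn(k, 2)
    pvals <- sample(c(stats::runif(ncol(pairs)),
                      stats::runif(ncol(pairs), 0, 0.1)), ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      pm[pairs[1, j], pairs[2, j]] <- pvals[j]
      pm[pairs[2, j], pairs[1, j]] <- pvals[j]
    }
    sig <- data.frame(a = nm[pairs[1, ]], b = nm[pairs[2, ]])[pvals < 0.05, ]
    letters <- cobind:::letter_display(nm, sig)
    for (j in seq_len(ncol(pairs))) {
      a <- nm[pairs[1, j]]
      b <- nm[pairs[2, j]]
      share <- length(intersect(strsplit(letters[[a]], "")[[1]],
                                strsplit(letters[[b]], "")[[1]])) > 0
      expect_equal(share, pm[a, b] >= 0.05,
                   info = paste("pair", a, b, "p", pm[a, b]))
    }
  }
})

test_that("median-of-ratios size factors are scale-equivariant", {
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2,
              dimnames = list(paste0("p", 1:3), c("s1", "s2")))
  expect_equal(unname(normalize_counts(m)$size_factors), c(1, 1))

  m2 <- m
  m2[, 2] <- m2[, 2] * 2L
  sf <- normalize_counts(m2)$size_factors
  expect_equal(unname(sf[2] / sf[1]), 2)

  # row permutation leaves size factors unchanged
  set.seed(25)
  m3 <- matrix(rpois(300, 50), ncol = 3,
               dimnames = list(paste0("p", 1:100), paste0("s", 1:3)))
  sf3 <- normalize_counts(m3)$size_factors
  expect_equal(normalize_counts(m3[sample(100), ])$size_factors, sf3)

  zero_row <- matrix(c(0L, 5L, 3L, 0L), ncol = 2,
                     dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(normalize_counts(zero_row), "library-size")
})

test_that("differential binding is antisymmetric in the condition labels", {
  peaks <- data.frame(id = sprintf("p%04d", 1:300))
  cm <- simulate_counts(peaks, sim_config(seed = 26, affected_fraction = 0.2))
  fwd <- differential_binding(cm$counts, cm$condition_of,
                              cond_order = c("wt", "pif4"))
  rev <- differential_binding(cm$counts, cm$condition_of,
                              cond_order = c("pif4", "wt"))
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$p, fwd$p)
  expect_equal(rev$fdr, fwd$fdr)
})

test_that("identical replicates with equal means give p = 1", {
  # two constant rows plus a mirrored pair, so every size factor is exactly 1
  m <- rbind(p1 = rep(5L, 6), p2 = rep(7L, 6),
             p3 = c(10L, 20L, 40L, 10L, 20L, 40L),
             p4 = c(40L, 20L, 10L, 40L, 20L, 10L))
  colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
  cond <- stats::setNames(rep(c("x", "y"), each = 3), colnames(m))
  expect_equal(unname(normalize_counts(m)$size_factors), rep(1, 6))
  for (moderate in c(TRUE, FALSE)) {
    db <- differential_binding(m, cond, moderate = moderate)
    expect_gte(db$p[db$peak_id == "p1"], 0.99)
    expect_equal(db$log2fc[db$peak_id == "p1"], 0)
  }
})

test_that("the unmoderated test is a plain Welch t", {
  set.seed(27)
  m <- matrix(rpois(600, 100), ncol = 6,
              dimnames = list(sprintf("p%03d", 1:100),
                              paste0("s", 1:6)))
  cond <- stats::setNames(rep(c("a", "b"), each = 3), colnames(m))
  db <- differential_binding(m, cond, moderate = FALSE,
                             cond_order = c("a", "b"))
  norm <- normalize_counts(m)$normalized
  l <- log2(norm + 0.5)
  for (i in c(1, 17, 99)) {
    ref <- stats::t.test(l[i, 4:6], l[i, 1:3])
    expect_equal(db$p[i], ref$p.value, tolerance = 1e-12)
    expect_equal(db$log2fc[i], mean(l[i, 4:6]) - mean(l[i, 1:3]),
                 tolerance = 1e-12)
  }
})

test_that("moderation rescues power that the plain Welch chain lacks at n = 3", {
  peaks <- data.frame(id = sprintf("p%04d", 1:1000))
  cfg <- sim_config(seed = 29, affected_fraction = 0.1, nb_dispersion = 0.1,
                    nb_mean = 100, effect_log2fc = 2)
  cm <- simulate_counts(peaks, cfg)
  aff <- peaks$id %in% cm$truth$affected_peak_ids
  mod <- differential_binding(cm$counts, cm$condition_of, moderate = TRUE)
  raw <- differential_binding(cm$counts, cm$condition_of, moderate = FALSE)
  sens_mod <- sum(mod$significant & aff) / sum(aff)
  sens_raw <- sum(raw$significant & aff) / sum(aff)
  expect_gte(sens_mod, 0.9)
  expect_lt(sens_raw, 0.5)
  fp <- sum(mod$significant & !aff)
  expect_lte(fp / max(sum(mod$significant), 1), 0.2)
})

test_that("moderated statistics track limma on one NB dataset", {
  skip_if_not_installed("limma")
  peaks <- data.frame(id = sprintf("p%04d", 1:500))
  cm <- simulate_counts(peaks, sim_config(seed = 28, affected_fraction = 0.1,
                                          nb_dispersion = 0.1))
  db <- differential_binding(cm$counts, cm$condition_of,
                             cond_order = c("wt", "pif4"))
  l <- log2(normalize_counts(cm$counts)$normalized + 0.5)
  design <- cbind(1, as.integer(cm$condition_of == "pif4"))
  fit <- limma::eBayes(limma::lmFit(l, design))
  p_limma <- fit$p.value[, 2]
  expect_gt(stats::cor(-log10(db$p), -log10(p_limma),
                       method = "spearman"), 0.99)
  top_mine <- head(order(db$p), 50)
  top_ref <- head(order(p_limma), 50)
  expect_gte(length(intersect(top_mine, top_ref)), 45)
})
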