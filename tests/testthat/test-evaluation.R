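test_that("ABC-like and distance baseline scores", {
  expect_equal(abc_like_score(4, 9, 100), 0.06)
  expect_equal(abc_like_score(0, 7, 50), 0)
  expect_equal(abc_like_score(2, 8, 1000), 4 / 1000)
  expect_warning(s <- abc_like_score(4, 9, 5), "clamped")
  expect_equal(s, 6 / 11)
  expect_equal(distance_score(100), 0.01)
  d <- sort(runif(20, 1, 1e6))
  expect_false(is.unsorted(rev(distance_score(d))))  # monotone decreasing
  expect_equal(order(distance_score(d)), order(d, decreasing = TRUE))
  expect_error(distance_score(0))
})

test_that("distance groups are half-open and partition (0, Inf)", {
  expect_equal(as.character(assign_distance_group(3000)), "0-5 kb")
  expect_equal(as.character(assign_distance_group(5000)), "5-50 kb")
  expect_equal(as.character(assign_distance_group(50000)), "50-1000 kb")
  expect_equal(as.character(assign_distance_group(2000000)), "1000 kb+")
  set.seed(90)
  d <- c(10^runif(200, 0, 7), 4999, 5000, 49999, 50000, 999999, 1000000)
  g <- assign_distance_group(d)
  expect_false(anyNA(g))          # every distance in exactly one group
  expect_equal(length(g), length(d))
})

test_that("gene-mapped negatives are the screened non-positives in range", {
  genes <- data.frame(gene_id = "G1", chrom = "chrS", tss = 2000000L)
  els <- data.frame(element_id = paste0("E", 1:6), chrom = "chrS",
                    start = c(1500000L, 1900000L, 2100000L, 2500000L,
                              2999950L, 3500000L),
                    end = c(1500100L, 1900100L, 2100100L, 2500100L,
                            3000050L, 3500100L))
  pos <- data.frame(gene_id = "G1", element_id = c("E2", "E3"))
  pr <- build_gene_mapped_negatives(pos, genes, els)
  # E6 is beyond 1 Mb; E5's midpoint sits exactly at the closed boundary
  expect_setequal(pr$element_id, paste0("E", 1:5))
  expect_equal(sum(pr$label), 2L)
  expect_equal(sum(pr$label == 0L), 3L)
  expect_true("E5" %in% pr$element_id)
  # no screened elements in range
  far <- data.frame(gene_id = "G2", element_id = "E9")
  genes2 <- rbind(genes, data.frame(gene_id = "G2", chrom = "chrS",
                                    tss = 9000000L))
  pr2 <- build_gene_mapped_negatives(far, genes2, els)
  expect_equal(nrow(pr2), 0L)
  # unknown gene skipped with count
  pr3 <- build_gene_mapped_negatives(
    data.frame(gene_id = "GX", element_id = "E1"), genes, els)
  expect_equal(attr(pr3, "n_skipped_genes"), 1L)
})

test_that("interaction labels require one anchor on each partner", {
  genes <- data.frame(gene_id = "G1", gene_start = 1000L, gene_end = 3000L)
  els <- data.frame(element_id = c("E1", "E2"), start = c(50000L, 80000L),
                    end = c(50350L, 80350L))
  pairs <- data.frame(gene_id = "G1", element_id = c("E1", "E2"))
  ints <- data.frame(start1 = 2000L, end1 = 2500L,
                     start2 = 50100L, end2 = 50200L)
  lab <- label_pairs_from_interactions(pairs, ints, genes, els)
  expect_equal(lab$label, c(1L, 0L))
  # swapped anchor order still labels positive
  ints_sw <- data.frame(start1 = 50100L, end1 = 50200L,
                        start2 = 2000L, end2 = 2500L)
  expect_equal(label_pairs_from_interactions(pairs, ints_sw, genes, els)$label,
               c(1L, 0L))
  # both anchors on the gene only: negative
  ints_g <- data.frame(start1 = 1100L, end1 = 1200L,
                       start2 = 2000L, end2 = 2100L)
  expect_equal(label_pairs_from_interactions(pairs, ints_g, genes, els)$label,
               c(0L, 0L))
})

test_that("auROC and auPRC match brute-force oracles", {
  # the 4-pair hand example
  s <- c(0.9, 0.8, 0.4, 0.2); l <- c(1, 0, 1, 0)
  expect_equal(auroc(s, l), 0.75)
  expect_equal(auroc(s, l), auroc_oracle(s, l))
  # perfect separation
  expect_equal(auroc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auprc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  # label-independent constant scores
  expect_equal(auroc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  # random instances up to 20 pairs, with ties
  set.seed(91)
  for (k in 1:25) {
    n <- sample(4:20, 1)
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    s <- sample(seq(0, 1, 0.1), n, TRUE)  # coarse grid forces ties
    expect_equal(auroc(s, l), auroc_oracle(s, l))
    expect_equal(auprc(s, l), auprc_oracle(s, l))
  }
  expect_true(is.nan(auroc(1:4, rep(1, 4))))
})

test_that("stratified metrics apply the size and class filters", {
  set.seed(92)
  mk <- function(gene, n, d_lo, d_hi, frac_pos) {
    data.frame(gene_id = gene, element_id = sprintf("%s_E%02d", gene, 1:n),
               distance = runif(n, d_lo, d_hi),
               label = as.integer(runif(n) < frac_pos))
  }
  pairs <- rbind(mk("G1", 15, 6000, 49000, 0.4),   # kept
                 mk("G1", 5, 100, 4000, 0.5),      # < 10 pairs: filtered
                 mk("G2", 12, 60000, 900000, 0.5)) # kept
  pairs$label[pairs$gene_id == "G2"] <- 0L         # single class: filtered
  pairs$score <- runif(nrow(pairs))
  m <- classify_metrics(pairs, "score", stratify = "gene_distance")
  expect_equal(nrow(m), 1L)
  expect_equal(m$gene_id, "G1")
  expect_equal(m$group, "5-50 kb")
  sk <- attr(m, "skipped")
  expect_true(any(grepl("min_n", unlist(sk))) &&
                any(grepl("single label", unlist(sk))))
  # pooled metrics agree with direct computation
  mp <- classify_metrics(pairs, "score", stratify = "none")
  expect_equal(mp$auroc, auroc(pairs$score, pairs$label))
})

test_that("precision/specificity at the mean-score cutoff", {
  r <- precision_specificity(c(0, 1), c(0, 1))
  expect_equal(r$threshold, 0.5)
  expect_equal(r$precision, 1.0)
  expect_equal(r$specificity, 1.0)
  # degenerate: no positives, nothing predicted positive above the mean
  r2 <- precision_specificity(c(1, 1, 1), c(0, 0, 0))
  expect_true(is.nan(r2$precision))
  expect_equal(r2$specificity, 1.0)
  # 6-pair hand table vs explicit confusion matrix
  s <- c(0.9, 0.7, 0.6, 0.4, 0.3, 0.1); l <- c(1, 0, 1, 1, 0, 0)
  thr <- mean(s)
  tp <- sum(s > thr & l == 1); fp <- sum(s > thr & l == 0)
  tn <- sum(s <= thr & l == 0)
  r3 <- precision_specificity(s, l)
  expect_equal(r3$precision, tp / (tp + fp))
  expect_equal(r3$specificity, tn / (tn + fp))
})

test_that("score-effect correlation is Spearman's rho", {
  s <- c(0.1, 0.5, 0.7, 0.9)
  expect_equal(score_correlation(s, -2 * s + 1), -1.0)
  # hand rank computation on a 4-point example
  eff <- c(0.3, -1, 2, 0.5)
  rho_hand <- cor(rank(s), rank(eff))
  expect_equal(score_correlation(s, eff), rho_hand)
  # independent permutations decorrelate
  set.seed(93)
  rho <- replicate(200, score_correlation(runif(30), runif(30)))
  expect_lt(abs(mean(rho)), 0.05)
  expect_true(is.nan(score_correlation(rep(1, 5), 1:5)))
})
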