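test_that("gene-to-cCRE scores normalise a gene's attention row", {
  A <- rbind(c(0.1, 1, 3, 5) / 9.1,
             c(0.2, 0.3, 0.4, 0.1),
             c(0.25, 0.25, 0.25, 0.25),
             c(0.1, 0.2, 0.3, 0.4))
  att <- fake_attention(A, kinds = c("gene", rep("element", 3)),
                        ids = c("G1", "E1", "E2", "E3"),
                        positions = c(10000L, 11000L, 50000L, 400000L))
  sc <- gene_to_cre_scores(att, normalization = "minmax")
  # raw row [1,3,5] (scaled) min-max normalises to [0, 0.5, 1]
  expect_equal(sc$attention, c(0, 0.5, 1))
  expect_equal(sc$raw_attention, c(1, 3, 5) / 9.1)
  expect_equal(sc$distance, c(1000, 40000, 390000))
  expect_equal(sc$adjusted_attention, sc$attention / log10(sc$distance))

  # softmax of equal logits is uniform
  Aeq <- A; Aeq[1, 2:4] <- 1 / 3
  atteq <- fake_attention(Aeq, kinds = c("gene", rep("element", 3)),
                          ids = c("G1", "E1", "E2", "E3"),
                          positions = c(10000L, 11000L, 50000L, 400000L))
  expect_equal(gene_to_cre_scores(atteq, "softmax")$attention, rep(1 / 3, 3))
  # single-class min-max degenerates to 0.5 with a warning
  expect_warning(sc1 <- gene_to_cre_scores(atteq, "minmax"), "constant")
  expect_equal(sc1$attention, rep(0.5, 3))
})

test_that("a 1-layer 1-head model's score is its attention entry", {
  set.seed(80)
  rc <- regulation_encoder_config(d_model = 16L, n_layers = 1L, n_heads = 1L,
                                  d_ff = 32L, dropout = 0)
  enc <- regulation_encoder(rc)
  E <- matrix(rnorm(3 * 16), 3, 16); rownames(E) <- paste0("E", 1:3)
  rf <- regulation_forward(enc, E, c(1000L, 50000L, 400000L), 100000L)
  sc <- gene_to_cre_scores(rf$attention, normalization = "softmax")
  expect_equal(sc$raw_attention, rf$attention$attention[[1]][[1]][1, 2:4],
               ignore_attr = TRUE)
})

test_that("distance adjustment follows score / log10(distance)", {
  expect_equal(adjust_by_distance(0.5, 1000), 0.5 / 3)
  expect_equal(adjust_by_distance(0, 123456), 0)
  # equal scores: the 1-kb pair outranks the 1-Mb pair by exactly 2x
  s <- adjust_by_distance(c(0.8, 0.8), c(1e3, 1e6))
  expect_equal(s[1] / s[2], 2)
  expect_warning(adjust_by_distance(1, 5), "clamped")
})

test_that("attention binning accumulates into genomic bins symmetrically", {
  # two elements in one bin, one in the next; hand-check the sums
  A <- matrix(c(0.0, 0.4, 0.1,
                0.6, 0.0, 0.2,
                0.3, 0.5, 0.0), 3, 3, byrow = TRUE)
  att <- fake_attention(A, kinds = rep("element", 3),
                        ids = paste0("E", 1:3),
                        positions = c(1000L, 6000L, 12000L))
  bm <- bin_attention(att, resolution = 10000L, normalize = FALSE)
  expect_equal(dim(bm$values), c(2L, 2L))
  # bin1 x bin1: pairs (1,1),(1,2),(2,1),(2,2) = 0+0.4+0.6+0 = 1.0
  expect_equal(bm$values[1, 1], 1.0)
  # bin1 x bin2 (symmetrised): ((0.1+0.2) + (0.3+0.5)) / 2
  expect_equal(bm$values[1, 2], 0.55)
  expect_equal(bm$values, t(bm$values))

  # single element occupies one bin
  att1 <- fake_attention(matrix(1), "element", "E1", 25000L)
  bm1 <- bin_attention(att1, resolution = 10000L, normalize = FALSE)
  expect_equal(bm1$values[3, 3], 1)
  expect_equal(sum(bm1$values), 1)
})

test_that("coarse binning is the block-sum of fine binning", {
  set.seed(81)
  n <- 12L
  A <- matrix(runif(n * n), n, n)
  pos <- sort(sample.int(80000L, n))
  att <- fake_attention(A, kinds = rep("element", n),
                        ids = sprintf("E%02d", 1:n), positions = pos)
  fine <- bin_attention(att, resolution = 10000L, normalize = FALSE)$values
  coarse <- bin_attention(att, resolution = 20000L, normalize = FALSE)$values
  # pad fine to an even number of bins then block-sum 2x2
  nf <- nrow(fine)
  nf2 <- 2L * nrow(coarse)
  pad <- matrix(0, nf2, nf2); pad[1:nf, 1:nf] <- fine
  block <- matrix(0, nrow(coarse), ncol(coarse))
  for (i in seq_len(nrow(coarse))) for (j in seq_len(ncol(coarse))) {
    block[i, j] <- sum(pad[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(coarse, block)
})

test_that("contact binning matches hand placement and round-trips", {
  pairs <- data.frame(start1 = 15000L, end1 = 16000L,
                      start2 = 65000L, end2 = 66000L, count = 5)
  bm <- bin_contacts(pairs, resolution = 10000L)
  expect_equal(bm$values[2, 7], 5)
  expect_equal(bm$values[7, 2], 5)
  expect_equal(sum(bm$values), 10)
  # no pairs -> zero matrix
  bm0 <- bin_contacts(pairs[0, , drop = FALSE], resolution = 10000L,
                      n_bins = 4L)
  expect_true(all(bm0$values == 0))
  # additivity over disjoint pair sets
  pairs2 <- data.frame(start1 = 5000L, end1 = 5100L, start2 = 35000L,
                       end2 = 35100L, count = 2)
  b12 <- bin_contacts(rbind(pairs, pairs2), resolution = 10000L)
  expect_equal(b12$values,
               bin_contacts(pairs, resolution = 10000L, n_bins = 7L)$values +
                 bin_contacts(pairs2, resolution = 10000L, n_bins = 7L)$values)
  # pairs emitted from a planted matrix reproduce it
  M <- simulate_contact_matrix(6L, boundaries = 3L, within = 2, between = 0)
  em <- which(upper.tri(M$values, diag = TRUE) & M$values > 0, arr.ind = TRUE)
  emitted <- data.frame(
    start1 = (em[, 1] - 1L) * 10000L + 2000L,
    end1 = (em[, 1] - 1L) * 10000L + 2100L,
    start2 = (em[, 2] - 1L) * 10000L + 7000L,
    end2 = (em[, 2] - 1L) * 10000L + 7100L,
    count = M$values[em])
  back <- bin_contacts(emitted, resolution = 10000L, n_bins = 6L)
  expect_equal(back$values, M$values)
})

test_that("binned matrices round-trip through dense TSV", {
  set.seed(84)
  M <- binned_matrix(matrix(round(runif(25), 6), 5, 5), resolution = 10000L,
                     offset = 20000L)
  p <- tempfile(fileext = ".tsv")
  write_matrix_tsv(M, p)
  back <- read_matrix_tsv(p)
  expect_equal(back$values, M$values, ignore_attr = TRUE)
  expect_equal(back$resolution, 10000L)
  expect_equal(back$offset, 20000L)
})

test_that("insulation is the off-diagonal 3x3 window sum", {
  ones <- matrix(1, 12, 12)
  expect_equal(insulation_score(ones, 6L), 9)
  expect_equal(insulation_score(matrix(0, 12, 12), 6L), 0)
  expect_true(is.nan(insulation_score(ones, 2L)))   # window out of range
  expect_true(is.nan(insulation_score(ones, 11L)))
  # noiseless two-block fixture: 0 at the boundary, 18 deep inside a block
  M <- simulate_contact_matrix(16L, boundaries = 8L, within = 2, between = 0)
  expect_equal(insulation_score(M, 8L), 0)
  expect_equal(insulation_score(M, 4L), 18)
  expect_equal(insulation_score(M, 12L), 18)
})

test_that("insulation profiles dip at planted boundaries only", {
  set.seed(82)
  bounds <- c(10L, 20L, 30L)
  M <- simulate_contact_matrix(40L, bounds, within = 2, between = 0.1,
                               noise_sd = 0.05)
  prof <- insulation_profile(M, bounds, flank = 4L)
  expect_equal(prof$score[prof$offset == 0], min(prof$score))
  expect_lt(prof$score[prof$offset == 0], prof$score[prof$offset == -1])
  expect_lt(prof$score[prof$offset == 0], prof$score[prof$offset == 1])
  # shuffled control boundaries show no minimum at offset 0
  shuf <- c(6L, 16L, 26L)
  prof_s <- insulation_profile(M, shuf, flank = 4L)
  expect_gt(prof_s$score[prof_s$offset == 0], min(prof_s$score))
})

test_that("CTCF pairs partition by topological relationship", {
  sch <- tiny_schema()
  mk <- function(id, start, type = "CTCF-only") candidate_element(
    genomic_interval("chrS", start, start + 100L), id, strrep("A", 100),
    matrix(0, 3, 100), sch, element_type = type)
  # 4 TADs with boundaries at 10k, 20k, 30k; anchors sit on boundaries
  boundaries <- data.frame(chrom = "chrS", start = c(10000L, 20000L, 30000L),
                           end = c(10001L, 20001L, 30001L))
  els <- list(mk("A1", 9950L), mk("A2", 19950L), mk("A3", 29950L),
              mk("N1", 15000L),   # non-anchor inside TAD 2
              mk("N2", 35000L))   # non-anchor inside TAD 4
  n <- length(els)
  A <- matrix(1 / n, n, n)
  att <- fake_attention(A, kinds = rep("element", n),
                        ids = vapply(els, `[[`, "", "element_id"),
                        positions = vapply(els, function(e)
                          interval_midpoint(e$interval), 0L))
  g <- group_ctcf_pairs(att, els, boundaries)
  # A1-A2 adjacent boundaries, A1-A3 two apart, A2-A3 adjacent
  expect_length(g[["anchor-to-anchor in adjacent TADs"]], 2L)
  expect_length(g[["anchor-to-anchor in remote TADs"]], 1L)
  # A1-N1 (N1 in TAD 2, flanking A1's boundary), A2-N1 same TAD
  expect_length(g[["anchor-to-non-anchor"]], 3L)  # A1-N1, A2-N1, A3-N2
  expect_length(g[["anchor-to-anchor"]], 0L)
  # two anchors on the same boundary
  els2 <- c(els, list(mk("A2b", 19990L)))
  att2 <- fake_attention(matrix(1 / 6, 6, 6), kinds = rep("element", 6),
                         ids = vapply(els2, `[[`, "", "element_id"),
                         positions = vapply(els2, function(e)
                           interval_midpoint(e$interval), 0L))
  g2 <- group_ctcf_pairs(att2, els2, boundaries)
  expect_length(g2[["anchor-to-anchor"]], 1L)
  expect_warning(group_ctcf_pairs(att, list(), boundaries), "no CTCF")
})

test_that("directional attention detects planted asymmetry", {
  set.seed(83)
  n <- 12L
  pos <- c(seq(10000L, 60000L, length.out = 6), # region A elements
           seq(210000L, 260000L, length.out = 6)) # region B elements
  base <- matrix(runif(n * n, 0.01, 0.03), n, n)
  base <- (base + t(base)) / 2
  A <- base
  A[1:6, 7:12] <- A[1:6, 7:12] + 0.25  # planted A->B excess
  mk_att <- function(M, tss = 150000L) fake_attention(
    rbind(0, cbind(0, M)), kinds = c("gene", rep("element", n)),
    ids = c("G", sprintf("E%02d", 1:n)),
    positions = c(tss, as.integer(pos)))
  att <- mk_att(A)
  ra <- genomic_interval("chrS", 5000L, 65000L)
  rb <- genomic_interval("chrS", 205000L, 265000L)
  # symmetric matrix: directions agree exactly
  rs <- directional_attention(mk_att(base), ra, rb)
  expect_equal(rs$score_ab, rs$score_ba)
  # background from 50 symmetric pseudo-genes
  bg <- lapply(1:50, function(k) {
    B <- matrix(runif(n * n, 0.01, 0.03), n, n); B <- (B + t(B)) / 2
    mk_att(B)
  })
  res <- directional_attention(att, ra, rb, background = bg)
  expect_gt(res$score_ab, res$score_ba)
  expect_lt(res$p_value, 0.05)
  expect_gt(length(res$background_diffs), 0L)
  # region with no cCRE errors
  expect_error(directional_attention(att, genomic_interval("chrS", 1, 2), rb),
               "no cCRE")
  # no background: scores without p-value
  expect_true(is.na(directional_attention(att, ra, rb)$p_value))
})
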