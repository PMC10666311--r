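# Benchmark machinery: baselines, pair-label construction and
# distance-stratified classification metrics.

#' Approximate Activity-by-Contact score
#'
#' Geometric mean of the element's summed H3K27ac and DNase signals,
#' multiplied by the reciprocal of the element-TSS distance.
#'
#' @param h3k27ac_sum,dnase_sum Summed track signal over the element
#'   (`>= 0`).
#' @param distance Element-TSS distance in bp; values below the 11-bp
#'   floor are clamped with a warning.
#' @return `sqrt(h3k27ac_sum * dnase_sum) / distance` (vectorised).
#' @examples
#' abc_like_score(4, 9, 100)  # 0.06
#' @export
abc_like_score <- function(h3k27ac_sum, dnase_sum, distance) {
  stopifnot(all(h3k27ac_sum >= 0), all(dnase_sum >= 0))
  if (any(distance < .DIST_FLOOR)) {
    warning("distance(s) below ", .DIST_FLOOR, " bp clamped to the floor")
    distance <- pmax(distance, .DIST_FLOOR)
  }
  sqrt(h3k27ac_sum * dnase_sum) / distance
}

#' Distance-only baseline score
#'
#' `1 / distance`: closer candidate pairs score higher. The ranking it
#' induces is exactly the reverse distance ranking.
#'
#' @param distance Positive distances in bp.
#' @return Numeric scores.
#' @export
distance_score <- function(distance) {
  stopifnot(all(distance > 0))
  1 / distance
}

#' Distance group of a candidate pair
#'
#' Half-open groups `[0, 5 kb)`, `[5, 50 kb)`, `[50, 1000 kb)`,
#' `[1000 kb, Inf)`; every positive distance maps to exactly one.
#'
#' @param distance Positive distances in bp.
#' @return Factor with levels `0-5 kb`, `5-50 kb`, `50-1000 kb`,
#'   `1000 kb+`.
#' @export
assign_distance_group <- function(distance) {
  stopifnot(all(distance > 0))
  cut(distance, breaks = c(0, 5e3, 5e4, 1e6, Inf), right = FALSE,
      labels = c("0-5 kb", "5-50 kb", "50-1000 kb", "1000 kb+"))
}

#' Gene-mapped negative pairs
#'
#' For each gene appearing in the positive set, every screened element
#' within 1 Mb of the gene's TSS (closed boundary) becomes a candidate
#' pair; candidates not in the positive set are labelled 0. Genes
#' without a TSS entry are skipped (count reported via attribute
#' `n_skipped_genes`).
#'
#' @param positives Data frame with `gene_id`, `element_id`.
#' @param genes Data frame with `gene_id`, `chrom`, `tss`.
#' @param elements Data frame with `element_id`, `chrom`, `start`,
#'   `end` (the screened element universe).
#' @param window Candidate window radius in bp (default 1 Mb, closed).
#' @return Data frame `gene_id`, `element_id`, `distance`, `label`.
#' @export
build_gene_mapped_negatives <- function(positives, genes, elements,
                                        window = 1000000L) {
  mid <- (elements$start + elements$end) %/% 2L
  skipped <- 0L
  out <- lapply(unique(positives$gene_id), function(g) {
    gr <- genes[genes$gene_id == g, , drop = FALSE]
    if (nrow(gr) == 0L) { skipped <<- skipped + 1L; return(NULL) }
    d <- mid - gr$tss[1L]
    keep <- elements$chrom == gr$chrom[1L] & abs(d) <= window
    if (!any(keep)) return(NULL)
    pos_ids <- positives$element_id[positives$gene_id == g]
    data.frame(gene_id = g, element_id = elements$element_id[keep],
               distance = pmax(abs(d[keep]), 1L),
               label = as.integer(elements$element_id[keep] %in% pos_ids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), element_id = character(),
                      distance = numeric(), label = integer())
  }
  attr(out, "n_skipped_genes") <- skipped
  out
}

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2

#' Label pairs from interaction anchor records
#'
#' A (gene, element) pair is positive iff some interaction record has
#' one anchor overlapping the gene body and the other overlapping the
#' element, in either anchor order.
#'
#' @param pairs Data frame with `gene_id`, `element_id`.
#' @param interactions Data frame with anchors `start1`, `end1`,
#'   `start2`, `end2` (single-chromosome; counts optional).
#' @param genes Data frame with `gene_id`, `gene_start`, `gene_end`
#'   (gene body interval).
#' @param elements Data frame with `element_id`, `start`, `end`.
#' @return `pairs` with a `label` column (1/0).
#' @export
label_pairs_from_interactions <- function(pairs, interactions, genes, elements) {
  gmap <- match(pairs$gene_id, genes$gene_id)
  emap <- match(pairs$element_id, elements$element_id)
  if (anyNA(gmap) || anyNA(emap)) stop("pair references unknown gene/element")
  lab <- vapply(seq_len(nrow(pairs)), function(i) {
    gs <- genes$gene_start[gmap[i]]; ge <- genes$gene_end[gmap[i]]
    es <- elements$start[emap[i]]; ee <- elements$end[emap[i]]
    hit <- (.overlaps(interactions$start1, interactions$end1, gs, ge) &
              .overlaps(interactions$start2, interactions$end2, es, ee)) |
           (.overlaps(interactions$start2, interactions$end2, gs, ge) &
              .overlaps(interactions$start1, interactions$end1, es, ee))
    as.integer(any(hit))
  }, 0L)
  pairs$label <- lab
  pairs
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) formulation; tied scores receive averaged
#' ranks, so label-independent constant scores give 0.5.
#'
#' @param scores Numeric scores (higher = predicted positive).
#' @param labels Binary labels.
#' @return auROC in `[0, 1]`, or `NaN` if a class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) return(NaN)
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation (average precision): thresholds descend over
#' unique score values and each recall increment is weighted by the
#' precision at that threshold.
#'
#' @inheritParams auroc
#' @return auPRC in `(0, 1]`, or `NaN` if no positives.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  if (np == 0L || length(labels) == 0L) return(NaN)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # group tied scores into single thresholds
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics, optionally stratified
#'
#' Computes auROC and auPRC of a score column against the `label`
#' column, either pooled (`stratify = "none"`) or separately per gene
#' and distance group (`stratify = "gene_distance"`), dropping strata
#' with fewer than `min_n` pairs or with a single label class (recorded
#' in the `skipped` attribute with a reason).
#'
#' @param pairs Data frame with `label`, `distance`, the score column
#'   and, for stratification, `gene_id`.
#' @param score_key Name of the score column.
#' @param stratify `"none"` or `"gene_distance"`.
#' @param min_n Minimum pairs per stratum (default 10, applied when
#'   stratifying).
#' @return Data frame with stratum identifiers, `n`, `n_pos`, `auroc`,
#'   `auprc`.
#' @export
classify_metrics <- function(pairs, score_key,
                             stratify = c("none", "gene_distance"),
                             min_n = 10L) {
  stratify <- match.arg(stratify)
  stopifnot(score_key %in% names(pairs))
  if (stratify == "none") {
    return(data.frame(n = nrow(pairs), n_pos = sum(pairs$label == 1L),
                      auroc = auroc(pairs[[score_key]], pairs$label),
                      auprc = auprc(pairs[[score_key]], pairs$label)))
  }
  pairs$.group <- assign_distance_group(pairs$distance)
  skipped <- list()
  out <- lapply(split(pairs, list(pairs$gene_id, pairs$.group), drop = TRUE),
                function(d) {
    key <- paste(d$gene_id[1L], d$.group[1L])
    if (nrow(d) < min_n) {
      skipped[[key]] <<- "fewer pairs than min_n"
      return(NULL)
    }
    if (length(unique(d$label)) < 2L) {
      skipped[[key]] <<- "single label class"
      return(NULL)
    }
    data.frame(gene_id = d$gene_id[1L], group = as.character(d$.group[1L]),
               n = nrow(d), n_pos = sum(d$label == 1L),
               auroc = auroc(d[[score_key]], d$label),
               auprc = auprc(d[[score_key]], d$label),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), group = character(),
                      n = integer(), n_pos = integer(), auroc = numeric(),
                      auprc = numeric())
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Precision and specificity at the mean-score cutoff
#'
#' Predicted positive iff `score > mean(scores)`. Undefined ratios
#' (empty denominators) are `NaN`.
#'
#' @inheritParams auroc
#' @return Named list `precision`, `specificity`, `threshold`.
#' @export
precision_specificity <- function(scores, labels) {
  stopifnot(length(scores) >= 1L)
  labels <- as.integer(labels)
  thr <- mean(scores)
  pred <- scores > thr
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  tn <- sum(!pred & labels == 0L)
  list(precision = if (tp + fp == 0L) NaN else tp / (tp + fp),
       specificity = if (tn + fp == 0L) NaN else tn / (tn + fp),
       threshold = thr)
}

#' Spearman correlation of scores with quantitative effects
#'
#' Rank correlation between an interaction score and a quantitative
#' per-pair effect (e.g. expression change on perturbation, which is
#' inversely related to enhancer strength, so a negative correlation is
#' the expected signature).
#'
#' @param scores Numeric scores.
#' @param effects Numeric effect values (same length, `>= 3`).
#' @return Spearman rho, `NaN` when either vector is constant.
#' @export
score_correlation <- function(scores, effects) {
  stopifnot(length(scores) == length(effects), length(scores) >= 3L)
  if (stats::sd(scores) == 0 || stats::sd(effects) == 0) return(NaN)
  stats::cor(scores, effects, method = "spearman")
}
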