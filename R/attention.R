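# Interpretation of regulation-encoder attention: gene-to-cCRE interaction
# scores, distance adjustment, 10-kb binned matrices, insulation profiles,
# CTCF anchor-pair grouping and directional enhancer-enhancer scores.

#' Binned square matrix at fixed genomic resolution
#'
#' @param values Square numeric matrix.
#' @param resolution Bin width in bp (default 10,000).
#' @param offset Genomic coordinate of the left edge of bin 1.
#' @return An object of class `binned_matrix`.
#' @export
binned_matrix <- function(values, resolution = 10000L, offset = 0L) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  structure(list(values = values, resolution = as.integer(resolution),
                 offset = as.integer(offset)),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("<binned_matrix %d x %d @ %d bp, offset %d>\n",
              nrow(x$values), ncol(x$values), x$resolution, x$offset))
  invisible(x)
}

# mean softmax attention over all layers and heads (the default reducer:
# the combination across the 4 layers x 4 heads is an arithmetic mean;
# "max" and a single layer are available for sensitivity checks)
.aggregate_attention <- function(attention, reducer = "mean", layer = NULL) {
  layers <- if (is.null(layer)) seq_along(attention$attention) else layer
  mats <- unlist(lapply(layers, function(l) attention$attention[[l]]),
                 recursive = FALSE)
  if (reducer == "mean") {
    Reduce(`+`, mats) / length(mats)
  } else if (reducer == "max") {
    Reduce(pmax, mats)
  } else stop("unknown reducer: ", reducer)
}

#' Gene-to-cCRE interaction scores from attention
#'
#' Focuses on attention from gene tokens to element tokens: for each
#' gene, the gene-query row of the aggregated (mean over layers and
#' heads) attention matrix, restricted to element columns, is the raw
#' score; min-max normalisation maps a gene's scores to `[0, 1]`
#' (constant scores map to 0.5, with a warning), softmax normalisation
#' to a distribution over the gene's elements. The distance-adjusted
#' score divides by `log10(distance)` (floored at 11 bp).
#'
#' @param attention An `attention_tensor` (from [forward_context()] or
#'   [regulation_forward()]).
#' @param normalization `"minmax"` or `"softmax"`.
#' @param reducer Aggregation over layers/heads: `"mean"` (default) or
#'   `"max"`.
#' @param layer Restrict to one layer (default all).
#' @return Data frame: `gene_id`, `element_id`, `distance` (bp, >= 1),
#'   `raw_attention`, `attention` (normalised), `adjusted_attention`.
#' @export
gene_to_cre_scores <- function(attention, normalization = c("minmax", "softmax"),
                               reducer = "mean", layer = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(attention, "attention_tensor"))
  tk <- attention$tokens
  gi <- which(tk$kind == "gene")
  ei <- which(tk$kind == "element")
  if (length(gi) < 1L) stop("attention tensor has no gene token")
  A <- .aggregate_attention(attention, reducer, layer)
  out <- lapply(gi, function(g) {
    raw <- A[g, ei]
    norm <- if (normalization == "minmax") {
      rng <- range(raw)
      if (length(raw) > 1L && rng[1L] < rng[2L]) {
        (raw - rng[1L]) / (rng[2L] - rng[1L])
      } else {
        warning("constant attention scores for gene ", tk$id[g],
                "; min-max normalisation returns 0.5")
        rep(0.5, length(raw))
      }
    } else {
      e <- exp(raw - max(raw)); e / sum(e)
    }
    d <- pmax(abs(tk$position[ei] - tk$position[g]), 1)
    data.frame(gene_id = tk$id[g], element_id = tk$id[ei], distance = d,
               raw_attention = unname(raw), attention = unname(norm),
               adjusted_attention = adjust_by_distance(unname(norm), d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Distance-adjust an interaction score
#'
#' Divides a score by `log10(distance)`; distances below the 11-bp floor
#' are clamped (with a warning) so the divisor stays above 1.
#'
#' @param score Numeric score(s).
#' @param distance_bp Genomic distance(s) in bp.
#' @return `score / log10(max(distance_bp, 11))`.
#' @export
adjust_by_distance <- function(score, distance_bp) {
  if (any(distance_bp < .DIST_FLOOR)) {
    warning("distance(s) below ", .DIST_FLOOR, " bp clamped to the floor")
  }
  score / .log10_dist(distance_bp)
}

#' Bin element-element attention at fixed resolution
#'
#' Min-max normalises the aggregated element-element attention matrix
#' over its entries, then sums it into genomic bins of `resolution` bp
#' by element anchor position (bins are aligned to coordinate 0), and
#' symmetrises by averaging with the transpose.
#'
#' @param attention An `attention_tensor`.
#' @param resolution Bin width in bp (default 10,000).
#' @param normalize Apply the min-max normalisation (default `TRUE`).
#' @param reducer Passed to the layer/head aggregation.
#' @return A [binned_matrix()].
#' @export
bin_attention <- function(attention, resolution = 10000L, normalize = TRUE,
                          reducer = "mean") {
  stopifnot(inherits(attention, "attention_tensor"))
  tk <- attention$tokens
  ei <- which(tk$kind == "element")
  if (length(ei) == 0L) stop("no element tokens to bin")
  A <- .aggregate_attention(attention, reducer)[ei, ei, drop = FALSE]
  if (normalize) {
    rng <- range(A)
    A <- if (rng[2L] > rng[1L]) (A - rng[1L]) / (rng[2L] - rng[1L])
         else A * 0
  }
  pos <- tk$position[ei]
  bins <- pos %/% resolution + 1L
  n_bins <- max(bins)
  # dense accumulation: sum A[i, j] into (bins[i], bins[j])
  M <- matrix(0, n_bins, n_bins)
  for (b in unique(bins)) {
    rows <- which(bins == b)
    contrib <- colSums(A[rows, , drop = FALSE])
    agg <- rowsum(contrib, bins)
    M[b, as.integer(rownames(agg))] <- M[b, as.integer(rownames(agg))] + agg[, 1L]
  }
  binned_matrix((M + t(M)) / 2, resolution = resolution, offset = 0L)
}

#' Bin contact pairs at fixed resolution
#'
#' Sums pair counts into genomic bins by anchor midpoint, symmetrically,
#' with the same bin convention as [bin_attention()] so the two matrices
#' are directly comparable.
#'
#' @param pairs Data frame with `start1`, `end1`, `start2`, `end2`,
#'   `count` (and optionally `chrom1`, `chrom2`).
#' @param resolution Bin width in bp.
#' @param chrom Chromosome to keep when `chrom1`/`chrom2` are present;
#'   off-chromosome pairs are skipped (count reported via attribute
#'   `n_skipped`).
#' @param n_bins Matrix size; default covers the largest anchor.
#' @return A [binned_matrix()].
#' @export
bin_contacts <- function(pairs, resolution = 10000L, chrom = NULL,
                         n_bins = NULL) {
  skipped <- 0L
  if (!is.null(chrom) && all(c("chrom1", "chrom2") %in% names(pairs))) {
    keep <- pairs$chrom1 == chrom & pairs$chrom2 == chrom
    skipped <- sum(!keep)
    pairs <- pairs[keep, , drop = FALSE]
  }
  m1 <- (pairs$start1 + pairs$end1) %/% 2L
  m2 <- (pairs$start2 + pairs$end2) %/% 2L
  b1 <- m1 %/% resolution + 1L
  b2 <- m2 %/% resolution + 1L
  if (is.null(n_bins)) n_bins <- max(1L, b1, b2)
  M <- matrix(0, n_bins, n_bins)
  for (i in seq_along(b1)) {
    M[b1[i], b2[i]] <- M[b1[i], b2[i]] + pairs$count[i]
    if (b1[i] != b2[i]) M[b2[i], b1[i]] <- M[b2[i], b1[i]] + pairs$count[i]
  }
  out <- binned_matrix(M, resolution = resolution, offset = 0L)
  attr(out, "n_skipped") <- skipped
  out
}

#' Read / write a binned matrix as dense TSV
#'
#' The interchange format is a dense tab-separated matrix with a header
#' row of bin start coordinates; resolution and offset are recovered
#' from the header.
#'
#' @param mat A [binned_matrix()].
#' @param path File path.
#' @return `path` (writer) or a `binned_matrix` (reader).
#' @export
write_matrix_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "binned_matrix"))
  starts <- mat$offset + (seq_len(nrow(mat$values)) - 1L) * mat$resolution
  df <- as.data.frame(mat$values)
  names(df) <- starts
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  starts <- as.integer(names(df))
  res <- if (length(starts) > 1L) starts[2L] - starts[1L] else 10000L
  binned_matrix(as.matrix(df), resolution = res, offset = starts[1L])
}

#' Insulation score at a boundary bin
#'
#' Sum of the 3x3 window one bin off the diagonal at the boundary: rows
#' `b-2 .. b` (the last three upstream bins), columns `b+1 .. b+3` (the
#' first three downstream bins), for the convention that the boundary
#' falls between bins `b` and `b+1`. With this placement the window
#' lies entirely across the boundary at exactly one bin, so the
#' boundary-centred profile has an unambiguous minimum. Dips at true
#' TAD boundaries where cross-boundary contact is depleted.
#' Out-of-range windows give `NaN`.
#'
#' @param mat A [binned_matrix()] (or plain square matrix).
#' @param boundary_bin 1-based bin index.
#' @return Window sum (a single number, `NaN` if out of range).
#' @export
insulation_score <- function(mat, boundary_bin) {
  V <- if (inherits(mat, "binned_matrix")) mat$values else mat
  b <- as.integer(boundary_bin)
  if (b - 2L < 1L || b + 3L > nrow(V)) return(NaN)
  sum(V[(b - 2L):b, (b + 1L):(b + 3L)])
}

#' Averaged insulation profile around boundaries
#'
#' Evaluates [insulation_score()] at every boundary shifted by offsets
#' `-flank .. flank` and averages over boundaries (NaN windows
#' excluded), producing the boundary-centred insulation curve.
#'
#' @param mat A [binned_matrix()] or square matrix.
#' @param boundaries Vector of 1-based boundary bins.
#' @param flank Half-width of the offset range (default 5 bins).
#' @return Data frame `offset`, `score`, `n` (boundaries contributing).
#' @export
insulation_profile <- function(mat, boundaries, flank = 5L) {
  offsets <- seq.int(-flank, flank)
  rows <- lapply(offsets, function(o) {
    v <- vapply(boundaries + o, function(b) insulation_score(mat, b), 0)
    v <- v[is.finite(v)]
    data.frame(offset = o, score = if (length(v)) mean(v) else NaN,
               n = length(v))
  })
  do.call(rbind, rows)
}

#' Group CTCF-bound element pairs by topological relationship
#'
#' Anchors are CTCF-bound elements whose interval intersects a TAD
#' boundary. Pairwise (symmetrised, unnormalised mean) attention between
#' CTCF-bound elements is split into: `anchor-to-anchor` (both on the
#' same boundary), `anchor-to-non-anchor` (anchor with a non-anchor in a
#' TAD flanking its boundary), `anchor-to-anchor in adjacent TADs`
#' (boundaries one apart) and `anchor-to-anchor in remote TADs`
#' (boundaries more than one TAD apart). Pairs fitting none of the rules
#' are omitted; the emitted groups are disjoint.
#'
#' @param attention An `attention_tensor` over the elements.
#' @param elements List of `candidate_element`s matching the element
#'   tokens (by id); CTCF binding is taken from `ctcf_ids` when given,
#'   otherwise from `element_type == "CTCF-only"`.
#' @param boundaries Data frame of boundary intervals (`chrom`, `start`,
#'   `end`), sorted by position.
#' @param ctcf_ids Optional character vector of CTCF-bound element ids.
#' @return Named list of numeric score vectors, one per group.
#' @export
group_ctcf_pairs <- function(attention, elements, boundaries,
                             ctcf_ids = NULL) {
  ids <- vapply(elements, `[[`, "", "element_id")
  if (is.null(ctcf_ids)) {
    ctcf_ids <- ids[vapply(elements, function(e)
      identical(e$element_type, "CTCF-only"), TRUE)]
  }
  groups <- list("anchor-to-anchor" = numeric(),
                 "anchor-to-non-anchor" = numeric(),
                 "anchor-to-anchor in adjacent TADs" = numeric(),
                 "anchor-to-anchor in remote TADs" = numeric())
  if (length(ctcf_ids) == 0L) {
    warning("no CTCF-bound elements")
    return(groups)
  }
  bstart <- sort(boundaries$start)
  bend <- boundaries$end[order(boundaries$start)]
  anchor_of <- function(e) {
    hit <- which(e$interval$start < bend & e$interval$end > bstart)
    if (length(hit)) hit[1L] else NA_integer_
  }
  keep <- ids %in% ctcf_ids
  els <- elements[keep]
  kid <- ids[keep]
  anc <- vapply(els, anchor_of, 0L)
  mids <- vapply(els, function(e) interval_midpoint(e$interval), 0L)
  tad <- findInterval(mids, bstart) + 1L # TAD id; boundary b separates b, b+1
  if (all(is.na(anc))) warning("no anchor elements intersect a boundary")

  tk <- attention$tokens
  ei <- which(tk$kind == "element")
  A <- .aggregate_attention(attention)[ei, ei, drop = FALSE]
  rownames(A) <- colnames(A) <- tk$id[ei]
  n <- length(els)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (!(kid[i] %in% rownames(A)) || !(kid[j] %in% rownames(A))) next
      s <- (A[kid[i], kid[j]] + A[kid[j], kid[i]]) / 2
      ai <- anc[i]; aj <- anc[j]
      grp <- if (!is.na(ai) && !is.na(aj)) {
        dd <- abs(ai - aj)
        if (dd == 0L) "anchor-to-anchor"
        else if (dd == 1L) "anchor-to-anchor in adjacent TADs"
        else "anchor-to-anchor in remote TADs"
      } else if (xor(is.na(ai), is.na(aj))) {
        b <- if (!is.na(ai)) ai else aj
        t_non <- if (!is.na(ai)) tad[j] else tad[i]
        if (t_non %in% c(b, b + 1L)) "anchor-to-non-anchor" else NA_character_
      } else NA_character_
      if (!is.na(grp)) groups[[grp]] <- c(groups[[grp]], s)
    }
  }
  groups
}

#' Directional attention between two regions
#'
#' Mean aggregated attention from the cCREs overlapping region A to
#' those overlapping region B, and the reverse. When background
#' attention tensors for other genes are supplied, element pairs at
#' matching signed TSS distances (within a tolerance of 20% of the
#' distance plus 5 kb) provide a null distribution of directional
#' differences, and a two-sided Mann-Whitney U test compares the focal
#' per-pair differences against it; with no matching background the
#' scores are reported without a p-value.
#'
#' @param attention `attention_tensor` of the focal gene's context.
#' @param region_a,region_b `genomic_interval`s (or lists of them).
#' @param background Optional list of `attention_tensor`s for other
#'   genes.
#' @return List with `score_ab`, `score_ba`, `pair_diffs`,
#'   `background_diffs`, `p_value`.
#' @export
directional_attention <- function(attention, region_a, region_b,
                                  background = NULL) {
  as_list <- function(r) if (inherits(r, "genomic_interval")) list(r) else r
  region_a <- as_list(region_a); region_b <- as_list(region_b)
  tk <- attention$tokens
  ei <- which(tk$kind == "element")
  g <- which(tk$kind == "gene")[1L]
  in_region <- function(regions) {
    sel <- vapply(tk$position[ei], function(p) {
      any(vapply(regions, function(r) p >= r$start && p < r$end, TRUE))
    }, TRUE)
    ei[sel]
  }
  ia <- in_region(region_a); ib <- in_region(region_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("a region overlaps no cCRE in the gene context")
  }
  A <- .aggregate_attention(attention)
  ab <- as.vector(A[ia, ib, drop = FALSE])
  ba <- as.vector(t(A[ib, ia, drop = FALSE]))
  pair_diffs <- ab - ba
  da <- tk$position[ia] - tk$position[g]
  db <- tk$position[ib] - tk$position[g]

  bg_diffs <- numeric()
  tol <- function(d) 0.2 * abs(d) + 5000
  for (bt in background %||% list()) {
    btk <- bt$tokens
    bei <- which(btk$kind == "element")
    bg_ <- which(btk$kind == "gene")[1L]
    bd <- btk$position[bei] - btk$position[bg_]
    BA <- .aggregate_attention(bt)
    for (u in seq_along(da)) {
      mu <- bei[abs(bd - da[u]) <= tol(da[u])]
      for (v in seq_along(db)) {
        mv <- bei[abs(bd - db[v]) <= tol(db[v])]
        for (x in mu) for (yy in setdiff(mv, x)) {
          bg_diffs <- c(bg_diffs, BA[x, yy] - BA[yy, x])
        }
      }
    }
  }
  p <- if (length(bg_diffs) >= 1L && length(pair_diffs) >= 1L) {
    suppressWarnings(stats::wilcox.test(pair_diffs, bg_diffs,
                                        exact = FALSE)$p.value)
  } else NA_real_
  list(score_ab = mean(ab), score_ba = mean(ba), pair_diffs = pair_diffs,
       background_diffs = bg_diffs, p_value = p)
}
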