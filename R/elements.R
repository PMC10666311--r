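#' Track schema
#'
#' Fixed, named ordering of the signal tracks attached to every element.
#' A track can be marked missing: its channel is kept (all zeros) so that
#' the model input shape is stable when an assay is unavailable.
#'
#' @param track_names Character vector of unique track names, e.g.
#'   `c("DNase", "H3K27ac", "CTCF")`.
#' @param missing Logical vector (same length) flagging absent assays.
#' @return An object of class `track_schema`.
#' @export
track_schema <- function(track_names, missing = rep(FALSE, length(track_names))) {
  track_names <- as.character(track_names)
  if (anyDuplicated(track_names)) stop("track names must be unique")
  n <- length(track_names)
  if (n < 1L) stop("schema needs at least one track")
  stopifnot(length(missing) == n)
  structure(list(track_names = track_names, n_tracks = n,
                 missing = as.logical(missing)),
            class = "track_schema")
}

#' Candidate cis-regulatory element
#'
#' The model's atomic input: one cCRE interval with its DNA sequence and
#' a per-base signal matrix (`n_tracks x length`, track order fixed by a
#' [track_schema()]).
#'
#' @param interval A `genomic_interval`.
#' @param element_id Identifier string.
#' @param sequence DNA string over `A,C,G,T,N`, same length as the
#'   interval.
#' @param signals Numeric matrix `n_tracks x length`, finite and >= 0.
#' @param schema A `track_schema` matching `nrow(signals)`.
#' @param element_type Optional label (e.g. `"distal-enhancer-like"`,
#'   `"CTCF-only"`).
#' @return An object of class `candidate_element`.
#' @export
candidate_element <- function(interval, element_id, sequence, signals, schema,
                              element_type = NA_character_) {
  stopifnot(inherits(interval, "genomic_interval"))
  sequence <- toupper(sequence)
  L <- interval_width(interval)
  if (nchar(sequence) != L) {
    stop("sequence length ", nchar(sequence), " != interval width ", L)
  }
  if (grepl("[^ACGTN]", sequence)) stop("sequence has characters outside ACGTN")
  signals <- as.matrix(signals)
  if (ncol(signals) != L) stop("signals must have one column per base")
  if (nrow(signals) != schema$n_tracks) {
    stop("signals have ", nrow(signals), " tracks, schema expects ",
         schema$n_tracks)
  }
  if (any(!is.finite(signals)) || any(signals < 0)) {
    stop("signal values must be finite and >= 0")
  }
  rownames(signals) <- schema$track_names
  structure(list(interval = interval, element_id = as.character(element_id),
                 sequence = sequence, signals = signals, schema = schema,
                 element_type = element_type),
            class = "candidate_element")
}

#' @export
print.candidate_element <- function(x, ...) {
  cat(sprintf("<cCRE %s %s:%d-%d, %d bp, %d tracks>\n", x$element_id,
              x$interval$chrom, x$interval$start, x$interval$end,
              interval_width(x$interval), nrow(x$signals)))
  invisible(x)
}

#' Pad or crop an element to a fixed length
#'
#' Elements are brought to a common length (350 bp by default) so they
#' batch into a fixed-shape tensor. Shorter elements are centre-padded:
#' `N` on the sequence, zeros on every signal track. Longer elements are
#' centre-cropped. When the length difference is odd the extra base goes
#' to (or comes off) the right side. The interval is updated symmetrically
#' so the midpoint anchor is unchanged (up to integer rounding).
#'
#' @param element A `candidate_element`.
#' @param target_len Target length in bp (default 350).
#' @return A `candidate_element` of width `target_len`.
#' @export
pad_element <- function(element, target_len = 350L) {
  L <- interval_width(element$interval)
  target_len <- as.integer(target_len)
  if (L == target_len) return(element)
  iv <- element$interval
  if (L < target_len) {
    left <- (target_len - L) %/% 2L
    right <- target_len - L - left
    seq2 <- paste0(strrep("N", left), element$sequence, strrep("N", right))
    sig2 <- cbind(matrix(0, nrow(element$signals), left),
                  element$signals,
                  matrix(0, nrow(element$signals), right))
    new_start <- max(0L, iv$start - left)
    iv2 <- genomic_interval(iv$chrom, new_start, new_start + target_len, iv$strand)
  } else {
    left <- (L - target_len) %/% 2L
    keep <- (left + 1L):(left + target_len)
    seq2 <- substr(element$sequence, left + 1L, left + target_len)
    sig2 <- element$signals[, keep, drop = FALSE]
    iv2 <- genomic_interval(iv$chrom, iv$start + left,
                            iv$start + left + target_len, iv$strand)
  }
  candidate_element(iv2, element$element_id, seq2, sig2, element$schema,
                    element$element_type)
}

#' Signed element-gene distance
#'
#' Element midpoint minus gene TSS, in bp. Negative = element upstream of
#' the TSS in reference orientation (strand is recorded on intervals but
#' does not enter distance computation).
#'
#' @param element A `candidate_element`.
#' @param tss Integer TSS position (0-based).
#' @return Signed integer distance.
#' @export
element_distance <- function(element, tss) {
  interval_midpoint(element$interval) - as.integer(tss)
}

#' Build a gene context
#'
#' Selects, among elements on the gene's chromosome, the `max_per_side`
#' nearest elements upstream and the `max_per_side` nearest downstream of
#' the TSS by absolute midpoint distance, and orders them by signed
#' distance. Ties at identical |distance| are broken deterministically by
#' (interval start, element_id), so the context is invariant to the order
#' in which elements are supplied.
#'
#' @param gene A list or one-row data frame with `gene_id`, `chrom`,
#'   `tss`, `expression`.
#' @param elements List of `candidate_element`s (same chromosome as the
#'   gene; others are dropped).
#' @param max_per_side Maximum number of elements kept on each side of
#'   the TSS (default 200, i.e. up to 400 per context).
#' @param max_distance Optional hard window in bp around the TSS;
#'   elements beyond it are excluded before the nearest-k selection.
#' @return An object of class `gene_context` with fields `gene`,
#'   `elements` (ordered list), `distances` (signed bp, ascending) and
#'   `element_ids`.
#' @export
build_gene_context <- function(gene, elements, max_per_side = 200L,
                               max_distance = Inf) {
  gene <- as.list(gene)
  keep <- vapply(elements, function(e) e$interval$chrom == gene$chrom, TRUE)
  elements <- elements[keep]
  d <- vapply(elements, element_distance, 0L, tss = gene$tss)
  ids <- vapply(elements, `[[`, "", "element_id")
  starts <- vapply(elements, function(e) e$interval$start, 0L)
  in_win <- abs(d) <= max_distance
  elements <- elements[in_win]; d <- d[in_win]
  ids <- ids[in_win]; starts <- starts[in_win]
  pick_side <- function(side_idx) {
    if (length(side_idx) == 0L) return(integer())
    o <- side_idx[order(abs(d[side_idx]), starts[side_idx], ids[side_idx])]
    o[seq_len(min(max_per_side, length(o)))]
  }
  sel <- c(pick_side(which(d < 0L)), pick_side(which(d >= 0L)))
  sel <- sel[order(d[sel], starts[sel], ids[sel])]
  if (length(sel) == 0L) {
    warning("empty context for gene ", gene$gene_id)
  }
  structure(list(gene = gene, elements = elements[sel],
                 distances = d[sel], element_ids = ids[sel]),
            class = "gene_context")
}

#' @export
print.gene_context <- function(x, ...) {
  cat(sprintf("<gene_context %s: %d elements, span %s bp>\n", x$gene$gene_id,
              length(x$elements),
              if (length(x$distances)) paste0(min(x$distances), "..",
                                              max(x$distances)) else "NA"))
  invisible(x)
}
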