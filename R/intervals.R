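#' Genomic interval
#'
#' Construct a genomic interval in 0-based, half-open coordinates (BED
#' convention, used everywhere inside the package).
#'
#' @param chrom Chromosome name.
#' @param start 0-based start (inclusive).
#' @param end End (exclusive); must be strictly greater than `start`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("chr1", 100, 450)
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop("interval coordinates must be integral")
  if (start < 0L) stop("interval start must be >= 0, got ", start)
  if (end <= start) stop("interval end must exceed start (", start, ", ", end, ")")
  if (!strand %in% c("+", "-", ".")) stop("strand must be one of '+', '-', '.'")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d%s>\n", x$chrom, x$start, x$end,
              if (x$strand == ".") "" else paste0("(", x$strand, ")")))
  invisible(x)
}

#' Interval width in bp
#' @param x A `genomic_interval`.
#' @return Integer width.
#' @export
interval_width <- function(x) x$end - x$start

#' Interval midpoint
#'
#' Anchor used for element-gene distances: `floor((start + end) / 2)`.
#' The midpoint is invariant under the symmetric padding applied by
#' [pad_element()], which is why it is the distance anchor.
#'
#' @param x A `genomic_interval`.
#' @return Integer position (0-based).
#' @export
interval_midpoint <- function(x) (x$start + x$end) %/% 2L

#' Read a BED file
#'
#' Reads >= 3 tab-separated columns into a data frame with 0-based
#' half-open coordinates, preserving input order. Columns 4-6 (name,
#' score, strand) are kept when present.
#'
#' @param path Path to a BED file.
#' @return A data frame with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3L) {
    bad <- which(lengths(fields) < 3L)[1L]
    stop("BED parse error at line ", bad, ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("BED parse error at line ", bad[1L], ": non-integer coordinates")
  }
  bad <- which(end <= start | start < 0L)
  if (length(bad) > 0L) {
    stop("BED validation error at line ", bad[1L], ": end <= start or start < 0")
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  ncols <- lengths(fields)
  if (all(ncols >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(ncols >= 5L)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  if (all(ncols >= 6L)) out$strand <- vapply(fields, `[[`, "", 6L)
  out
}

#' Write intervals to BED
#'
#' Inverse of [read_bed()]: coordinates round-trip bit-exactly.
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand` columns.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand")) {
    if (extra %in% names(intervals)) cols <- c(cols, extra) else break
  }
  mat <- do.call(cbind, lapply(intervals[cols], function(x) {
    if (is.numeric(x)) format(x, trim = TRUE, scientific = FALSE) else as.character(x)
  }))
  writeLines(if (nrow(intervals) == 0L) character() else
               apply(matrix(mat, nrow = nrow(intervals)), 1L, paste, collapse = "\t"),
             path)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @return Data frame with columns `chrom`, `start`, `end`, `value`,
#'   0-based half-open.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer", "numeric"))
  if (nrow(df) > 0L && any(df$end <= df$start)) {
    stop("bedGraph validation error: record with end <= start")
  }
  df
}

.track_df <- function(track) {
  if (is.character(track)) track <- read_bedgraph(track)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  track
}

#' Per-base signal over an interval
#'
#' Expands a bedGraph track to a per-base vector over `interval`;
#' positions not covered by any record are 0. Overlapping records are an
#' error (the value at a base would be ambiguous).
#'
#' @param track A bedGraph path or a data frame as from [read_bedgraph()].
#' @param interval A `genomic_interval`.
#' @param n_bins Number of output bins; defaults to the interval width
#'   (per-base). When smaller, per-base values are averaged within
#'   equal-width bins.
#' @return Numeric vector of length `n_bins`.
#' @export
read_signal_bedgraph <- function(track, interval, n_bins = interval_width(interval)) {
  df <- .track_df(track)
  df <- df[df$chrom == interval$chrom &
             df$start < interval$end & df$end > interval$start, , drop = FALSE]
  L <- interval_width(interval)
  v <- numeric(L)
  if (nrow(df) > 0L) {
    df <- df[order(df$start), , drop = FALSE]
    if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)])) {
      stop("overlapping bedGraph records over ", interval$chrom, ":",
           interval$start, "-", interval$end, " (ambiguous value)")
    }
    for (i in seq_len(nrow(df))) {
      a <- max(df$start[i], interval$start) - interval$start + 1L
      b <- min(df$end[i], interval$end) - interval$start
      v[a:b] <- df$value[i]
    }
  }
  if (n_bins == L) return(v)
  stopifnot(n_bins >= 1L)
  idx <- ceiling(seq_along(v) / (L / n_bins))
  as.numeric(tapply(v, idx, mean))
}

#' Sum of track signal over an interval
#'
#' Per-base accumulation of a bedGraph track across an interval: the sum
#' of record values weighted by the width of their overlap with the
#' interval. Used to compute element-level H3K27ac / DNase activity for
#' the Activity-by-Contact style baseline.
#'
#' @inheritParams read_signal_bedgraph
#' @return A single number.
#' @export
sum_signal_over_interval <- function(track, interval) {
  df <- .track_df(track)
  df <- df[df$chrom == interval$chrom &
             df$start < interval$end & df$end > interval$start, , drop = FALSE]
  if (nrow(df) == 0L) return(0)
  ov <- pmin(df$end, interval$end) - pmax(df$start, interval$start)
  sum(df$value * ov)
}

#' Write a bedGraph track
#'
#' @param df Data frame with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(df, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end,
                   format(df$value, trim = TRUE, scientific = FALSE, digits = 10))
  writeLines(if (nrow(df) == 0L) character() else lines, path)
  invisible(path)
}

#' Read a gene expression table
#'
#' Tab-separated with header `gene_id`, `chrom`, `tss`, `expression`
#' (and optionally `count`). `tss` is a 0-based position; `expression`
#' is log1p of summed transcript TPM (or of a count in synthetic data).
#'
#' @param path Path to the TSV.
#' @return Data frame of gene records.
#' @export
read_genes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "expression")
  if (!all(need %in% names(df))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$expression < 0)) stop("expression must be >= 0 (log1p scale)")
  df
}

#' Write a gene expression table
#' @param genes Data frame as from [read_genes_tsv()].
#' @param path Output path.
#' @export
write_genes_tsv <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pair-label table
#'
#' Tab-separated with header `gene_id`, `element_id`, `label`,
#' `distance` (bp, positive).
#'
#' @param path Path to the TSV.
#' @return Data frame of pair records.
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "element_id", "label", "distance")
  if (!all(need %in% names(df))) {
    stop("pair table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0/1")
  df
}
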