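# Synthetic regulatory landscapes with planted ground truth.
#
# One chromosome carrying non-overlapping cCREs and genes whose Poisson
# expression rate is a log10-distance-decayed sum of planted regulator
# effects; signal tracks encode activity (DNase), regulator strength
# (H3K27ac) and TAD-boundary elements (CTCF), so trained models can be
# tested for recovery of the planted structure.

#' Simulation configuration
#'
#' @param seed RNG seed; all outputs are deterministic given it.
#' @param chrom_len Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param n_genes Number of genes.
#' @param n_elements Number of cCREs (non-overlapping).
#' @param element_len Element width in bp (padded model length).
#' @param n_tracks Number of signal tracks (>= 3: DNase, H3K27ac, CTCF,
#'   then pure-noise tracks).
#' @param regulators_per_gene Planted regulators sampled per gene.
#' @param max_link_distance Maximum TSS-regulator distance in bp; must
#'   not exceed `chrom_len / 2`.
#' @param effect_scale Multiplier on the summed regulator contribution to
#'   the expression rate.
#' @param baseline_rate Expression rate of an unregulated gene.
#' @param noise_sd SD of the additive (truncated-at-0) signal noise.
#' @param motif 8-mer planted at the centre of regulator elements.
#' @param n_tads Number of TADs (boundaries are `n_tads - 1` internal
#'   positions).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, chrom_len = 5000000L, chrom = "chrS",
                       n_genes = 50L, n_elements = 2000L, element_len = 350L,
                       n_tracks = 5L, regulators_per_gene = 4L,
                       max_link_distance = 1000000L, effect_scale = 5,
                       baseline_rate = 4, noise_sd = 0.3,
                       motif = "TGACGTCA", n_tads = 5L) {
  stopifnot(n_genes >= 1L, n_elements >= 1L, element_len >= 10L,
            n_tracks >= 3L, regulators_per_gene >= 0L, n_tads >= 1L,
            effect_scale >= 0, baseline_rate > 0, noise_sd >= 0)
  if (max_link_distance > chrom_len / 2) {
    stop("max_link_distance must be <= chrom_len / 2")
  }
  structure(as.list(environment()), class = "sim_config")
}

.default_track_names <- function(n_tracks) {
  base <- c("DNase", "H3K27ac", "CTCF", "H3K4me3", "H3K4me1")
  if (n_tracks <= length(base)) base[seq_len(n_tracks)]
  else c(base, paste0("track", seq_len(n_tracks - length(base))))
}

# floor for log10-distance terms; avoids blow-ups within ~10 bp of a TSS
.DIST_FLOOR <- 11

.log10_dist <- function(d) log10(pmax(abs(d), .DIST_FLOOR))

# unimodal per-base bump, peak 1 at the element centre
.bump <- function(L) {
  i <- seq_len(L)
  exp(-0.5 * ((i - (L + 1) / 2) / (L / 8))^2)
}

#' Simulate a regulatory landscape with planted ground truth
#'
#' Generative model (deterministic given `config$seed`): element
#' activities `a_e ~ LogNormal(0, 1)`; each gene draws
#' `regulators_per_gene` regulators among elements within
#' `max_link_distance` of its TSS with probability proportional to
#' `1 / log10(max(|d|, 11))`, with element-level effects
#' `w_e ~ LogNormal(0, 0.5)` (one effect per element, shared by every
#' gene that element regulates); the expression rate is
#' `mu_g = baseline_rate + effect_scale * sum_e w_e a_e / log10(max(|d|, 11))`
#' and the observed count is `y_g ~ Poisson(mu_g)`, stored as
#' `log1p(y_g)` (the raw count is kept too). The DNase track is an
#' `a_e`-scaled bump plus truncated noise; H3K27ac scales with the
#' element's planted effect (zero for non-regulators before
#' noise); CTCF is high only for TAD-boundary elements; any further
#' tracks are pure noise. Regulator elements carry `config$motif` at
#' their centre.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genome` with `elements` (list of padded
#'   `candidate_element`s), `genes` (data frame: gene_id, chrom, tss,
#'   expression, count), `truth` (links, element_activity,
#'   tad_boundaries as 10-kb bin indices, boundary_positions,
#'   expected_rate), `schema` and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_elements
  L <- config$element_len
  slack <- config$chrom_len - n * L
  if (slack < 0) {
    stop("infeasible placement: ", n, " elements of ", L,
         " bp exceed chromosome length ", config$chrom_len)
  }
  starts <- floor(sort(stats::runif(n, 0, slack))) + (seq_len(n) - 1L) * L
  mids <- starts + L %/% 2L
  element_ids <- sprintf("E%05d", seq_len(n))
  activity <- stats::rlnorm(n, 0, 1)
  # element-level regulatory effect w_e, shared by every gene the element
  # regulates; the H3K27ac track reads it out directly
  w_elem <- stats::rlnorm(n, 0, 0.5)

  # genes: TSS placed quasi-evenly (stratified with jitter) so candidate
  # windows tile the chromosome instead of clumping, with margins so a
  # full window fits when possible
  lo <- min(config$max_link_distance, config$chrom_len %/% 4L)
  hi <- config$chrom_len - lo
  jit <- stats::runif(config$n_genes, -0.3, 0.3)
  tss <- sort(floor(lo + (hi - lo) *
                      (seq_len(config$n_genes) - 0.5 + jit) / config$n_genes))
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))

  # TAD boundaries (genomic positions, and bin indices at 10 kb)
  n_bound <- config$n_tads - 1L
  boundary_pos <- if (n_bound > 0L) {
    sort(floor(config$chrom_len * (seq_len(n_bound) / config$n_tads) +
                 stats::runif(n_bound, -0.02, 0.02) * config$chrom_len))
  } else integer()
  boundary_elems <- if (n_bound > 0L) {
    unique(vapply(boundary_pos, function(p) which.min(abs(mids - p)), 0L))
  } else integer()

  # planted links
  links <- vector("list", config$n_genes)
  mu <- rep(config$baseline_rate, config$n_genes)
  for (g in seq_len(config$n_genes)) {
    if (config$regulators_per_gene == 0L) { links[[g]] <- NULL; next }
    d <- mids - tss[g]
    cand <- which(abs(d) <= config$max_link_distance)
    k <- min(config$regulators_per_gene, length(cand))
    if (k == 0L) { links[[g]] <- NULL; next }
    sel <- cand[sample.int(length(cand), k, prob = 1 / .log10_dist(d[cand]))]
    w <- w_elem[sel]
    mu[g] <- mu[g] + config$effect_scale *
      sum(w * activity[sel] / .log10_dist(d[sel]))
    links[[g]] <- data.frame(gene_id = gene_ids[g], element_id = element_ids[sel],
                             effect = w, distance = d[sel],
                             stringsAsFactors = FALSE)
  }
  links <- if (length(links) && !all(vapply(links, is.null, TRUE))) {
    do.call(rbind, links[!vapply(links, is.null, TRUE)])
  } else {
    data.frame(gene_id = character(), element_id = character(),
               effect = numeric(), distance = integer())
  }
  y <- stats::rpois(config$n_genes, mu)

  # regulator elements carry their effect on the H3K27ac track
  w_total <- numeric(n)
  reg_idx <- match(unique(links$element_id), element_ids)
  w_total[reg_idx] <- w_elem[reg_idx]

  schema <- track_schema(.default_track_names(config$n_tracks))
  bump <- .bump(L)
  is_boundary <- seq_len(n) %in% boundary_elems
  is_regulator <- w_total > 0
  bases <- c("A", "C", "G", "T")
  motif_chars <- strsplit(toupper(config$motif), "")[[1L]]
  seq_mat <- matrix(sample(bases, n * L, replace = TRUE), n, L)
  noise <- function() {
    if (config$noise_sd == 0) 0 else stats::rnorm(L, 0, config$noise_sd)
  }
  elements <- vector("list", n)
  for (i in seq_len(n)) {
    sig <- matrix(0, config$n_tracks, L)
    sig[1L, ] <- pmax(activity[i] * bump + noise(), 0)
    sig[2L, ] <- pmax(w_total[i] * bump + noise(), 0)
    sig[3L, ] <- pmax((if (is_boundary[i]) 3 else 0) * bump + noise(), 0)
    if (config$n_tracks > 3L) {
      for (k in 4L:config$n_tracks) sig[k, ] <- pmax(0 * bump + noise(), 0)
    }
    sq <- seq_mat[i, ]
    if (is_regulator[i]) {
      at <- (L - length(motif_chars)) %/% 2L
      sq[(at + 1L):(at + length(motif_chars))] <- motif_chars
    }
    etype <- if (is_boundary[i]) "CTCF-only"
      else if (is_regulator[i]) "distal-enhancer-like" else "other"
    elements[[i]] <- candidate_element(
      genomic_interval(config$chrom, starts[i], starts[i] + L),
      element_ids[i], paste(sq, collapse = ""), sig, schema,
      element_type = etype)
  }
  genes <- data.frame(gene_id = gene_ids, chrom = config$chrom, tss = tss,
                      expression = log1p(y), count = y,
                      stringsAsFactors = FALSE)
  truth <- list(links = links,
                element_activity = stats::setNames(activity, element_ids),
                element_effect = stats::setNames(w_total, element_ids),
                tad_boundaries = as.integer(boundary_pos %/% 10000L),
                boundary_positions = boundary_pos,
                boundary_element_ids = element_ids[boundary_elems],
                expected_rate = stats::setNames(mu, gene_ids))
  structure(list(elements = elements, genes = genes, truth = truth,
                 schema = schema, config = config),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome %s (%g bp): %d genes, %d elements, %d links>\n",
              x$config$chrom, x$config$chrom_len, nrow(x$genes),
              length(x$elements), nrow(x$truth$links)))
  invisible(x)
}

#' Simulate a block-structured contact matrix
#'
#' Square symmetric matrix with value `within` for bin pairs inside the
#' same TAD and `between` across TADs, plus symmetric Gaussian noise
#' clipped at 0. A boundary index `b` means the boundary falls between
#' bins `b` and `b + 1` (1-based).
#'
#' @param n_bins Matrix dimension.
#' @param boundaries Strictly increasing bin indices in
#'   `[1, n_bins - 1]`.
#' @param within Contact value within a TAD (`> between`).
#' @param between Contact value across TADs (`>= 0`).
#' @param noise_sd SD of the symmetric additive noise (default 0).
#' @return A [binned_matrix()] at 10-kb nominal resolution.
#' @export
simulate_contact_matrix <- function(n_bins, boundaries = integer(),
                                    within = 2, between = 0,
                                    noise_sd = 0) {
  boundaries <- as.integer(boundaries)
  if (length(boundaries)) {
    if (any(diff(boundaries) <= 0L)) stop("boundaries must be strictly increasing")
    if (any(boundaries < 1L | boundaries > n_bins - 1L)) {
      stop("boundary index out of range [1, n_bins - 1]")
    }
  }
  stopifnot(within > between, between >= 0)
  tad <- findInterval(seq_len(n_bins) - 0.5, boundaries) # 0-based TAD id
  M <- matrix(between, n_bins, n_bins)
  same <- outer(tad, tad, `==`)
  M[same] <- within
  if (noise_sd > 0) {
    R <- matrix(stats::rnorm(n_bins^2, 0, noise_sd), n_bins)
    M <- pmax(M + (R + t(R)) / 2, 0)
  }
  binned_matrix(M, resolution = 10000L, offset = 0L)
}

#' Write a simulated landscape as standard files
#'
#' Emits, under `dir`: `elements.bed` (cCREs with ids), one bedGraph per
#' track (`signal_<track>.bedGraph`, nonzero per-base values),
#' `genome.fasta` (full chromosome; element spans carry the element
#' sequences), `expression.tsv`, `links.tsv` (planted ground truth) and
#' `tad_boundaries.bed`. Everything is re-readable with the package's
#' readers and round-trips losslessly.
#'
#' @param sim A `sim_genome`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- sim$config
  paths <- list()

  iv <- data.frame(
    chrom = cfg$chrom,
    start = vapply(sim$elements, function(e) e$interval$start, 0L),
    end = vapply(sim$elements, function(e) e$interval$end, 0L),
    name = vapply(sim$elements, `[[`, "", "element_id"),
    stringsAsFactors = FALSE)
  paths$elements <- file.path(dir, "elements.bed")
  write_bed(iv, paths$elements)

  for (k in seq_len(sim$schema$n_tracks)) {
    nz_list <- lapply(sim$elements, function(e) which(e$signals[k, ] > 0))
    starts <- unlist(mapply(function(e, nz) e$interval$start + nz - 1L,
                            sim$elements, nz_list, SIMPLIFY = FALSE))
    vals <- unlist(mapply(function(e, nz) e$signals[k, nz],
                          sim$elements, nz_list, SIMPLIFY = FALSE))
    recs <- data.frame(chrom = rep(cfg$chrom, length(starts)),
                       start = as.integer(starts),
                       end = as.integer(starts) + 1L,
                       value = as.numeric(vals), stringsAsFactors = FALSE)
    p <- file.path(dir, paste0("signal_", sim$schema$track_names[k], ".bedGraph"))
    write_bedgraph(recs, p)
    paths[[paste0("track_", sim$schema$track_names[k])]] <- p
  }
  paths$tracks <- file.path(dir, "tracks.txt")
  writeLines(sim$schema$track_names, paths$tracks) # preserves schema order

  set.seed(cfg$seed + 777L) # background sequence stream, independent of sim draws
  genome <- sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE)
  for (e in sim$elements) {
    genome[(e$interval$start + 1L):e$interval$end] <-
      strsplit(e$sequence, "")[[1L]]
  }
  dss <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(dss) <- cfg$chrom
  paths$fasta <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(dss, paths$fasta)

  paths$expression <- file.path(dir, "expression.tsv")
  write_genes_tsv(sim$genes, paths$expression)

  paths$links <- file.path(dir, "links.tsv")
  utils::write.table(sim$truth$links, paths$links, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  bdf <- data.frame(chrom = cfg$chrom, start = sim$truth$boundary_positions,
                    end = sim$truth$boundary_positions + 1L,
                    stringsAsFactors = FALSE)
  paths$boundaries <- file.path(dir, "tad_boundaries.bed")
  write_bed(bdf, paths$boundaries)

  invisible(paths)
}

#' Load a fixture bundle back into memory
#'
#' Inverse of [write_fixture_bundle()]: reconstructs the elements (with
#' sequences from the FASTA and per-base signals from the bedGraphs),
#' the gene table and the planted links, producing a list usable by
#' [make_dataset()].
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return List with `elements`, `genes`, `schema`, `truth` (links and
#'   boundary positions only).
#' @export
load_fixture_bundle <- function(dir) {
  bed <- read_bed(file.path(dir, "elements.bed"))
  manifest <- file.path(dir, "tracks.txt")
  track_names <- if (file.exists(manifest)) readLines(manifest) else {
    sub("^signal_", "", sub("\\.bedGraph$", "",
                            list.files(dir, pattern = "^signal_.*\\.bedGraph$")))
  }
  schema <- track_schema(track_names)
  tracks <- lapply(track_names, function(tn) {
    read_bedgraph(file.path(dir, paste0("signal_", tn, ".bedGraph")))
  })
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fasta"))
  genome <- fa[[1L]]
  elements <- lapply(seq_len(nrow(bed)), function(i) {
    iv <- genomic_interval(bed$chrom[i], bed$start[i], bed$end[i])
    sig <- do.call(rbind, lapply(tracks, read_signal_bedgraph, interval = iv))
    candidate_element(
      iv, bed$name[i],
      as.character(Biostrings::subseq(genome, iv$start + 1L, iv$end)),
      sig, schema)
  })
  genes <- read_genes_tsv(file.path(dir, "expression.tsv"))
  links_path <- file.path(dir, "links.tsv")
  links <- if (file.exists(links_path)) {
    utils::read.table(links_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL
  bpath <- file.path(dir, "tad_boundaries.bed")
  bpos <- if (file.exists(bpath)) read_bed(bpath)$start else integer()
  list(elements = elements, genes = genes, schema = schema,
       truth = list(links = links, boundary_positions = bpos))
}
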