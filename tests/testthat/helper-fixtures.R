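# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except through tempfiles created inside tests.

tiny_schema <- function() track_schema(c("DNase", "H3K27ac", "CTCF"))

random_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                                collapse = "")

tiny_element <- function(id, start, L = 20L, chrom = "chrS",
                         schema = tiny_schema(), signals = NULL) {
  if (is.null(signals)) signals <- matrix(abs(rnorm(schema$n_tracks * L)),
                                          schema$n_tracks, L)
  candidate_element(genomic_interval(chrom, start, start + L), id,
                    random_dna(L), signals, schema)
}

# small model: d_model 16, short elements, dropout 0 for determinism
tiny_model <- function(seed = 7L, L = 20L, d_model = 16L, reg_layers = 2L,
                       dropout = 0) {
  set.seed(seed)
  ec <- element_encoder_config(d_model = d_model, n_layers = 2L, n_heads = 2L,
                               d_ff = 2L * d_model, dropout = dropout,
                               rel_pos_buckets = 8L, rel_pos_max_distance = 16L,
                               element_len = L)
  rc <- regulation_encoder_config(d_model = d_model, n_layers = reg_layers,
                                  n_heads = 2L, d_ff = 2L * d_model,
                                  dropout = dropout, rel_pos_buckets = 16L)
  attnreg_model(ec, rc, tiny_schema())
}

tiny_context <- function(n_elements = 4L, seed = 11L, L = 20L, tss = 500000L) {
  set.seed(seed)
  starts <- sort(sample.int(900000L, n_elements)) + 1000L
  els <- lapply(seq_len(n_elements), function(i)
    tiny_element(sprintf("E%02d", i), starts[i], L))
  gene <- list(gene_id = "G1", chrom = "chrS", tss = tss,
               expression = log1p(5))
  build_gene_context(gene, els)
}

# hand-built attention tensor: `mats` is a matrix or list-of-lists
# (layers -> heads); token kinds/ids/positions given explicitly
fake_attention <- function(mats, kinds, ids, positions) {
  if (is.matrix(mats)) mats <- list(list(mats))
  structure(list(attention = mats, logits = mats,
                 tokens = data.frame(kind = kinds, id = ids,
                                     position = positions,
                                     stringsAsFactors = FALSE),
                 n_genes = sum(kinds == "gene")),
            class = "attention_tensor")
}

# brute-force metric oracles, independent of the package implementations
auroc_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  if (!length(sp) || !length(sn)) return(NaN)
  tot <- 0
  for (p in sp) for (n in sn) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(sp) * length(sn))
}

auprc_oracle <- function(scores, labels) {
  np <- sum(labels == 1)
  if (np == 0) return(NaN)
  ap <- 0; prev_rec <- 0
  for (t in sort(unique(scores), decreasing = TRUE)) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / np
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}
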