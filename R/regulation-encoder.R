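#' Regulation encoder configuration
#'
#' Hyperparameters of the context transformer that models gene-cCRE and
#' cCRE-cCRE interactions: 4 layers, 4 heads by default. Tokens are one
#' shared learnable \[GENE\] embedding per gene plus the element
#' embeddings; genes are distinguished only by their TSS coordinate,
#' which enters attention as a bucketed signed genomic distance
#' (T5 scheme, saturating at `rel_pos_max_distance`).
#'
#' @param d_model Embedding width; must match the element encoder.
#' @param n_layers Transformer layers (default 4).
#' @param n_heads Attention heads (default 4).
#' @param d_ff Feed-forward width (default `4 * d_model`).
#' @param dropout Dropout rate during training (default 0.1).
#' @param rel_pos_buckets Distance buckets (default 64).
#' @param rel_pos_max_distance Saturation distance in bp (default 1e6,
#'   the candidate window radius).
#' @return A config list of class `regulation_encoder_config`.
#' @export
regulation_encoder_config <- function(d_model = 256L, n_layers = 4L,
                                      n_heads = 4L, d_ff = 4L * d_model,
                                      dropout = 0.1, rel_pos_buckets = 64L,
                                      rel_pos_max_distance = 1000000L) {
  stopifnot(d_model %% n_heads == 0L)
  structure(list(d_model = as.integer(d_model), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
                 dropout = dropout, rel_pos_buckets = as.integer(rel_pos_buckets),
                 rel_pos_max_distance = as.integer(rel_pos_max_distance)),
            class = "regulation_encoder_config")
}

#' Gene-gene attention mask
#'
#' To keep information flow gene-independent, attention between distinct
#' gene tokens is blocked; a gene token may still attend itself and all
#' element tokens, and element tokens attend everything. Token order is
#' genes first, then elements.
#'
#' @param n_genes Number of gene tokens.
#' @param n_elements Number of element tokens.
#' @param block_element_to_gene Additionally block element-to-gene
#'   attention, making gene tokens pure readout queries: element
#'   representations are then independent of which genes share the
#'   context, so a multi-gene context is exactly equivalent to the
#'   per-gene contexts. This is the mask the model uses; the default
#'   `FALSE` gives the minimal gene-gene mask.
#' @return Logical `(n_genes+n_elements)` square matrix, `TRUE` = blocked.
#' @export
build_gene_gene_mask <- function(n_genes, n_elements,
                                 block_element_to_gene = FALSE) {
  Tn <- n_genes + n_elements
  M <- matrix(FALSE, Tn, Tn)
  g <- seq_len(n_genes)
  if (n_genes > 1L) {
    M[g, g] <- TRUE
    diag(M)[g] <- FALSE
  }
  if (block_element_to_gene && n_genes > 0L && n_elements > 0L) {
    M[(n_genes + 1L):Tn, g] <- TRUE
  }
  M
}

#' Create a regulation encoder
#'
#' @param config A [regulation_encoder_config()].
#' @return An object of class `regulation_encoder`. Initialisation draws
#'   from the current RNG state.
#' @export
regulation_encoder <- function(config = regulation_encoder_config()) {
  d <- config$d_model
  structure(list(config = config,
                 params = list(
                   gene_token = stats::rnorm(d, 0, 0.02),
                   enc = .init_encoder(d, config$n_layers, config$n_heads,
                                       config$d_ff, config$rel_pos_buckets),
                   head = list(w = stats::rnorm(d, 0, 0.02), b = 0))),
            class = "regulation_encoder")
}

#' Forward pass of the regulation encoder
#'
#' Builds the token sequence (\[GENE\] tokens, then element embeddings),
#' applies the gene-gene mask, runs the transformer, and returns each
#' gene token's output representation together with the attention tensor
#' (per-layer, per-head softmax weights and biased logits over all token
#' pairs).
#'
#' @param model A [regulation_encoder()].
#' @param element_embs Matrix `n_elements x d_model` of element
#'   representations (rownames = element ids), or a 0-row matrix for an
#'   empty context.
#' @param element_pos Integer vector of element anchor coordinates (bp).
#' @param tss_pos Integer vector of gene TSS coordinates (one per gene).
#' @param gene_ids Optional character vector of gene ids for the
#'   attention metadata.
#' @param training Keep caches and apply dropout.
#' @param keep_attention Return the attention tensor (default `TRUE`).
#' @return List with `gene_out` (`n_genes x d_model`), `attention` (an
#'   `attention_tensor` or `NULL`) and, when training, `cache`.
#' @export
regulation_forward <- function(model, element_embs, element_pos, tss_pos,
                               gene_ids = NULL, training = FALSE,
                               keep_attention = TRUE) {
  cfg <- model$config
  n_ele <- nrow(element_embs)
  n_genes <- length(tss_pos)
  stopifnot(n_genes >= 1L, length(element_pos) == n_ele)
  if (n_ele == 0L) {
    warning("empty context: gene output computed from the [GENE] token alone")
  }
  gene_rows <- matrix(model$params$gene_token, n_genes, cfg$d_model,
                      byrow = TRUE)
  x <- rbind(gene_rows, element_embs, deparse.level = 0L)
  pos <- c(as.numeric(tss_pos), as.numeric(element_pos))
  buckets <- .bucket_matrix(pos, cfg$rel_pos_buckets, cfg$rel_pos_max_distance)
  mask <- build_gene_gene_mask(n_genes, n_ele, block_element_to_gene = TRUE)
  ef <- .encoder_forward(x, model$params$enc, buckets, cfg$n_heads, mask = mask,
                         dropout = cfg$dropout, training = training,
                         keep_attention = keep_attention)
  tokens <- data.frame(
    kind = rep(c("gene", "element"), c(n_genes, n_ele)),
    id = c(if (is.null(gene_ids)) paste0("gene", seq_len(n_genes)) else gene_ids,
           if (n_ele) rownames(element_embs) else character()),
    position = pos, stringsAsFactors = FALSE)
  att <- NULL
  if (keep_attention) {
    att <- structure(list(attention = ef$attention, logits = ef$logits,
                          tokens = tokens, n_genes = n_genes),
                     class = "attention_tensor")
  }
  list(gene_out = ef$out[seq_len(n_genes), , drop = FALSE],
       attention = att,
       cache = if (training) list(enc = ef$cache, n_genes = n_genes,
                                  n_ele = n_ele, x = x))
}

.regulation_backward <- function(model, d_gene_out, cache) {
  Tn <- cache$n_genes + cache$n_ele
  dout <- matrix(0, Tn, ncol(d_gene_out))
  dout[seq_len(cache$n_genes), ] <- d_gene_out
  eb <- .encoder_backward(dout, cache$enc, model$params$enc,
                          model$config$n_heads)
  list(grads = list(gene_token = colSums(eb$dx[seq_len(cache$n_genes), ,
                                               drop = FALSE]),
                    enc = eb$grads,
                    head = list(w = numeric(ncol(d_gene_out)), b = 0)),
       d_element_embs = eb$dx[-seq_len(cache$n_genes), , drop = FALSE])
}

#' Predict expression from a gene representation
#'
#' Linear projection followed by softplus, so the predicted rate is
#' strictly positive (the mean of the Poisson observation model).
#'
#' @param model A [regulation_encoder()].
#' @param gene_emb Matrix `n_genes x d_model` (or a single vector).
#' @return Numeric vector of predicted rates, all `> 0`.
#' @export
predict_expression <- function(model, gene_emb) {
  if (is.null(dim(gene_emb))) gene_emb <- matrix(gene_emb, 1L)
  z <- drop(gene_emb %*% model$params$head$w) + model$params$head$b
  softplus(z)
}

#' Poisson negative log-likelihood
#'
#' `mean(lambda - y * log(lambda))` over the batch; the `log(y!)` term is
#' constant in the parameters and omitted. Targets may be non-integer
#' (e.g. log1p-normalised expression treated as a count-like value).
#'
#' @param lambda Predicted rates, all `> 0`.
#' @param y Observed targets, all `>= 0`.
#' @return Mean loss (a single number).
#' @examples
#' poisson_nll(1, 0)        # 1
#' poisson_nll(exp(1), 2)   # e - 2
#' @export
poisson_nll <- function(lambda, y) {
  if (any(lambda <= 0)) stop("poisson_nll requires lambda > 0")
  if (any(y < 0)) stop("poisson_nll requires y >= 0")
  stopifnot(length(lambda) == length(y))
  mean(lambda - y * log(lambda))
}
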