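#' Element encoder configuration
#'
#' Hyperparameters of the per-element transformer: 2 layers, 4 heads and
#' a 256-channel embedding by default, with a learnable \[CLS\] token
#' whose output is the element representation. Relative position between
#' bases enters attention as a T5-style bucketed bias.
#'
#' @param d_model Embedding width (default 256; must divide by `n_heads`).
#' @param n_layers Number of transformer encoder layers (default 2).
#' @param n_heads Attention heads per layer (default 4).
#' @param d_ff Feed-forward hidden width (default `4 * d_model`).
#' @param dropout Dropout rate during training (default 0.1).
#' @param rel_pos_buckets Buckets for the relative-position bias
#'   (default 32).
#' @param rel_pos_max_distance Saturation distance of the bucketing, in
#'   bases (default 128; element scale).
#' @param element_len Fixed padded element length in bp (default 350).
#' @param log1p_signals Apply `log1p` to signal values before the linear
#'   projection (default `FALSE`; inputs are assumed already normalised,
#'   e.g. read-depth normalised DNase or fold-change ChIP).
#' @return A config list of class `element_encoder_config`.
#' @export
element_encoder_config <- function(d_model = 256L, n_layers = 2L, n_heads = 4L,
                                   d_ff = 4L * d_model, dropout = 0.1,
                                   rel_pos_buckets = 32L,
                                   rel_pos_max_distance = 128L,
                                   element_len = 350L,
                                   log1p_signals = FALSE) {
  stopifnot(d_model %% n_heads == 0L)
  structure(list(d_model = as.integer(d_model), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
                 dropout = dropout, rel_pos_buckets = as.integer(rel_pos_buckets),
                 rel_pos_max_distance = as.integer(rel_pos_max_distance),
                 onehot_dim = 5L, element_len = as.integer(element_len),
                 log1p_signals = log1p_signals),
            class = "element_encoder_config")
}

#' One-hot encode a DNA sequence
#'
#' Row order follows the fixed code `A, T, C, G, N`; exactly one 1 per
#' row. Lowercase input is accepted and uppercased.
#'
#' @param sequence A string over `A,T,C,G,N`.
#' @return Numeric matrix `L x 5`.
#' @examples
#' onehot_encode("A")  # 1 0 0 0 0
#' @export
onehot_encode <- function(sequence) {
  code <- c(A = 1L, T = 2L, C = 3L, G = 4L, N = 5L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  idx <- code[chars]
  if (anyNA(idx)) {
    stop("sequence has characters outside ATCGN: ",
         paste(unique(chars[is.na(idx)]), collapse = ""))
  }
  M <- matrix(0, length(idx), 5L, dimnames = list(NULL, names(code)))
  M[cbind(seq_along(idx), idx)] <- 1
  M
}

.init_element_encoder <- function(config, n_tracks) {
  d <- config$d_model
  list(W_dna = .glorot(config$onehot_dim, d), b_dna = numeric(d),
       W_sig = .glorot(n_tracks, d), b_sig = numeric(d),
       cls = stats::rnorm(d, 0, 0.02),
       enc = .init_encoder(d, config$n_layers, config$n_heads, config$d_ff,
                           config$rel_pos_buckets))
}

#' Per-base embedding of one element
#'
#' The per-base embedding is the sum of a DNA embedding (linear
#' projection of the one-hot sequence) and a signal embedding (linear
#' projection of the per-base track values). The learned \[CLS\] vector
#' is prepended as row 1.
#'
#' @param onehot Matrix `L x 5` from [onehot_encode()].
#' @param signals Matrix `n_tracks x L` of track values.
#' @param params Element-encoder parameter list (fields `W_dna`, `b_dna`,
#'   `W_sig`, `b_sig`, `cls`).
#' @return Matrix `(L + 1) x d_model`; row 1 is the \[CLS\] embedding.
#' @export
embed_basepairs <- function(onehot, signals, params) {
  if (ncol(signals) != nrow(onehot)) {
    stop("signals and sequence disagree on element length")
  }
  if (nrow(signals) != nrow(params$W_sig)) {
    stop("element has ", nrow(signals), " tracks, encoder expects ",
         nrow(params$W_sig))
  }
  emb <- .addb(onehot %*% params$W_dna, params$b_dna) +
    .addb(crossprod(signals, params$W_sig), params$b_sig)
  rbind(params$cls, emb, deparse.level = 0L)
}

# token positions: [CLS] = 0, base i = i; bucket matrices are memoised per
# length because they depend only on L and the config
.element_buckets <- function(model, L) {
  key <- as.character(L)
  if (is.null(model$bucket_env[[key]])) {
    cfg <- model$config
    model$bucket_env[[key]] <- .bucket_matrix(0:L, cfg$rel_pos_buckets,
                                              cfg$rel_pos_max_distance)
  }
  model$bucket_env[[key]]
}

#' Create an element encoder
#'
#' @param config An [element_encoder_config()].
#' @param n_tracks Number of signal tracks (from the track schema).
#' @return An object of class `element_encoder` holding all parameters.
#'   Initialisation draws from the current RNG state; seed it for
#'   reproducibility.
#' @export
element_encoder <- function(config = element_encoder_config(), n_tracks) {
  structure(list(config = config, n_tracks = as.integer(n_tracks),
                 params = .init_element_encoder(config, n_tracks),
                 bucket_env = new.env(parent = emptyenv())),
            class = "element_encoder")
}

.element_forward <- function(model, onehot, signals, training = FALSE) {
  cfg <- model$config
  if (cfg$log1p_signals) signals <- log1p(signals)
  emb <- embed_basepairs(onehot, signals, model$params)
  buckets <- .element_buckets(model, nrow(onehot))
  ef <- .encoder_forward(emb, model$params$enc, buckets, cfg$n_heads,
                         dropout = cfg$dropout, training = training)
  list(emb = ef$out[1L, ], cache = if (training)
    list(enc = ef$cache, onehot = onehot, signals = signals, Tn = nrow(emb)))
}

.element_backward <- function(model, d_emb, cache) {
  dout <- matrix(0, cache$Tn, length(d_emb))
  dout[1L, ] <- d_emb
  eb <- .encoder_backward(dout, cache$enc, model$params$enc,
                          model$config$n_heads)
  dX <- eb$dx
  dEmb_bp <- dX[-1L, , drop = FALSE]
  list(W_dna = crossprod(cache$onehot, dEmb_bp), b_dna = colSums(dEmb_bp),
       W_sig = cache$signals %*% dEmb_bp, b_sig = colSums(dEmb_bp),
       cls = dX[1L, ],
       enc = eb$grads)
}

#' Encode one element
#'
#' Runs the element transformer in evaluation mode (dropout off) and
#' returns the \[CLS\] output, the fixed-length element representation.
#' Deterministic given the parameters.
#'
#' @param element A padded `candidate_element` whose width equals the
#'   encoder's `element_len`.
#' @param model An [element_encoder()] (or an [attnreg_model()], whose
#'   element encoder is used).
#' @return Numeric vector of length `d_model`.
#' @export
encode_element <- function(element, model) {
  if (inherits(model, "attnreg_model")) model <- model$element
  L <- interval_width(element$interval)
  if (L != model$config$element_len) {
    stop("element width ", L, " != configured length ",
         model$config$element_len, "; call pad_element() first")
  }
  .element_forward(model, onehot_encode(element$sequence),
                   element$signals)$emb
}

#' Encode a list of elements into an embedding matrix
#'
#' @param elements List of padded `candidate_element`s.
#' @param model An [element_encoder()].
#' @return Matrix `n_elements x d_model` with element ids as rownames.
#' @export
encode_elements <- function(elements, model) {
  if (inherits(model, "attnreg_model")) model <- model$element
  embs <- vapply(elements, encode_element, numeric(model$config$d_model),
                 model = model)
  M <- t(matrix(embs, nrow = model$config$d_model))
  rownames(M) <- vapply(elements, `[[`, "", "element_id")
  M
}
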