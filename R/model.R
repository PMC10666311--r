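#' Full expression model (element encoder + regulation encoder)
#'
#' Couples an [element_encoder()] with a [regulation_encoder()] that
#' share `d_model`. Initialisation draws from the current RNG; call
#' `set.seed()` first for reproducible weights.
#'
#' @param element_config An [element_encoder_config()].
#' @param regulation_config A [regulation_encoder_config()].
#' @param schema A [track_schema()] fixing the signal tracks.
#' @return An object of class `attnreg_model`.
#' @export
attnreg_model <- function(element_config = element_encoder_config(),
                          regulation_config = regulation_encoder_config(),
                          schema) {
  stopifnot(element_config$d_model == regulation_config$d_model)
  structure(list(element = element_encoder(element_config, schema$n_tracks),
                 regulation = regulation_encoder(regulation_config),
                 schema = schema),
            class = "attnreg_model")
}

#' @export
print.attnreg_model <- function(x, ...) {
  cat(sprintf(paste0("<attnreg_model d=%d | element: %dL/%dH | ",
                     "regulation: %dL/%dH | tracks: %s>\n"),
              x$element$config$d_model, x$element$config$n_layers,
              x$element$config$n_heads, x$regulation$config$n_layers,
              x$regulation$config$n_heads,
              paste(x$schema$track_names, collapse = ",")))
  invisible(x)
}

.context_positions <- function(context) {
  vapply(context$elements, function(e) interval_midpoint(e$interval), 0L)
}

#' Forward pass over one gene context
#'
#' Encodes the context's elements (or reuses precomputed embeddings),
#' runs the regulation encoder and the prediction head, and returns the
#' predicted expression rate with, optionally, the attention tensor.
#'
#' @param model An [attnreg_model()].
#' @param context A `gene_context`.
#' @param element_embs Optional matrix of precomputed element embeddings
#'   (rownames = element ids, as from [encode_elements()]); when given,
#'   elements are looked up instead of re-encoded.
#' @param keep_attention Also return the attention tensor.
#' @return List with `lambda` (predicted rate), `gene_out` and
#'   `attention`.
#' @export
forward_context <- function(model, context, element_embs = NULL,
                            keep_attention = FALSE) {
  .forward_context_impl(model, context, element_embs,
                        training = FALSE, keep_attention = keep_attention)
}

.forward_context_impl <- function(model, context, element_embs = NULL,
                                  training = FALSE, keep_attention = FALSE) {
  ids <- context$element_ids
  ele_caches <- NULL
  if (is.null(element_embs)) {
    d <- model$element$config$d_model
    E <- matrix(0, length(ids), d)
    if (training) ele_caches <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      el <- context$elements[[i]]
      fw <- .element_forward(model$element, onehot_encode(el$sequence),
                             el$signals, training = training)
      E[i, ] <- fw$emb
      if (training) ele_caches[[i]] <- fw$cache
    }
    rownames(E) <- ids
  } else {
    miss <- setdiff(ids, rownames(element_embs))
    if (length(miss)) stop("no precomputed embedding for: ",
                           paste(utils::head(miss, 3L), collapse = ", "))
    E <- element_embs[ids, , drop = FALSE]
  }
  pos <- .context_positions(context)
  rf <- regulation_forward(model$regulation, E, pos,
                           tss_pos = context$gene$tss,
                           gene_ids = context$gene$gene_id,
                           training = training,
                           keep_attention = keep_attention)
  z <- drop(rf$gene_out %*% model$regulation$params$head$w) +
    model$regulation$params$head$b
  list(lambda = softplus(z), gene_out = rf$gene_out, attention = rf$attention,
       z = z,
       cache = if (training) list(reg = rf$cache, ele = ele_caches, ids = ids))
}

# Backward through head + regulation encoder (+ element encoder when joint).
# d_lambda: gradient of the scalar loss wrt each gene's predicted rate.
.backward_context <- function(model, fwd, d_lambda, joint = FALSE) {
  dz <- d_lambda * .sigmoid(fwd$z)
  hw <- model$regulation$params$head$w
  d_gene_out <- outer(dz, hw)
  rb <- .regulation_backward(model$regulation, d_gene_out, fwd$cache$reg)
  rb$grads$head <- list(w = drop(crossprod(fwd$gene_out, dz)), b = sum(dz))
  egrads <- NULL
  if (joint) {
    for (i in seq_along(fwd$cache$ele)) {
      g <- .element_backward(model$element, rb$d_element_embs[i, ],
                             fwd$cache$ele[[i]])
      egrads <- if (is.null(egrads)) g else .tree_add(egrads, g)
    }
  }
  list(element = egrads, regulation = rb$grads)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds all parameters, both configs, the track schema
#' and any metadata supplied; reloading reproduces evaluation-mode
#' outputs exactly.
#'
#' @param model An [attnreg_model()].
#' @param path File path.
#' @param meta Optional list of metadata (step, validation metrics, ...).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  m <- model
  m$element$bucket_env <- NULL
  saveRDS(list(model = m, meta = meta, version = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return For `load_checkpoint()`, a list with `model` and `meta`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  ck$model$element$bucket_env <- new.env(parent = emptyenv())
  class(ck$model) <- "attnreg_model"
  ck[c("model", "meta")]
}
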