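# Numerical core: linear algebra building blocks for the two encoders.
# Everything is plain base-R matrices; backward passes are written by hand
# and verified against finite differences in the test suite.

.addb <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

.glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Numerically stable softplus
#' @param x Numeric vector.
#' @return `log(1 + exp(x))`, computed without overflow.
#' @export
softplus <- function(x) {
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax
#'
#' Rows may contain `-Inf` (masked logits); a row that is entirely
#' `-Inf` is an error because no key is attendable.
#'
#' @param S Numeric matrix of logits.
#' @return Matrix of the same shape; every row sums to 1.
#' @export
row_softmax <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  if (any(!is.finite(m))) stop("attention row with no unmasked keys")
  E <- exp(S - m)
  E / rowSums(E)
}

#' T5-style relative position bucket
#'
#' Maps a signed relative position to one of `n_buckets` buckets:
#' half the buckets for each sign, exact buckets for small |P| and
#' logarithmically spaced buckets out to `max_distance`, beyond which the
#' index saturates. Deterministic and vectorised.
#'
#' @param rel Integer vector of signed relative positions.
#' @param n_buckets Total number of buckets (even, >= 4).
#' @param max_distance Distance at which bucketing saturates.
#' @return Integer vector of 0-based bucket indices in `[0, n_buckets)`.
#' @export
t5_relative_bucket <- function(rel, n_buckets = 32L, max_distance = 128L) {
  stopifnot(n_buckets >= 4L, n_buckets %% 2L == 0L, max_distance > 1)
  n2 <- n_buckets %/% 2L
  ret <- ifelse(rel > 0, n2, 0L)
  rp <- abs(as.numeric(rel))
  max_exact <- n2 %/% 2L
  large <- max_exact +
    floor(log(pmax(rp, 1) / max_exact) / log(max_distance / max_exact) *
            (n2 - max_exact))
  large <- pmin(large, n2 - 1L)
  as.integer(ret + ifelse(rp < max_exact, rp, large))
}

# 1-based T x T bucket index matrix for positions `pos` (bp or token index)
.bucket_matrix <- function(pos, n_buckets, max_distance) {
  P <- outer(pos, pos, `-`)
  matrix(t5_relative_bucket(as.vector(P), n_buckets, max_distance) + 1L,
         length(pos), length(pos))
}

# --- parameter initialisation -----------------------------------------------

.init_attn <- function(d_model, n_heads, n_buckets) {
  list(Wq = .glorot(d_model, d_model), bq = numeric(d_model),
       Wk = .glorot(d_model, d_model), bk = numeric(d_model),
       Wv = .glorot(d_model, d_model), bv = numeric(d_model),
       Wo = .glorot(d_model, d_model), bo = numeric(d_model),
       bias = matrix(0, n_buckets, n_heads))
}

.init_layer <- function(d_model, n_heads, d_ff, n_buckets) {
  list(ln1 = list(g = rep(1, d_model), b = numeric(d_model)),
       attn = .init_attn(d_model, n_heads, n_buckets),
       ln2 = list(g = rep(1, d_model), b = numeric(d_model)),
       ffn = list(W1 = .glorot(d_model, d_ff), b1 = numeric(d_ff),
                  W2 = .glorot(d_ff, d_model), b2 = numeric(d_model)))
}

.init_encoder <- function(d_model, n_layers, n_heads, d_ff, n_buckets) {
  list(layers = lapply(seq_len(n_layers), function(i)
         .init_layer(d_model, n_heads, d_ff, n_buckets)),
       lnf = list(g = rep(1, d_model), b = numeric(d_model)))
}

# --- elementary forward/backward --------------------------------------------

.ln_forward <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  sd_ <- sqrt(v + eps)
  xhat <- xc / sd_
  list(out = .addb(sweep(xhat, 2L, p$g, `*`), p$b), xhat = xhat, sd = sd_)
}

.ln_backward <- function(dy, cache, p) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, p$g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) / cache$sd
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

.dropout_forward <- function(x, p_drop, training) {
  if (!training || p_drop <= 0) return(list(out = x, mask = NULL))
  m <- matrix((stats::runif(length(x)) >= p_drop) / (1 - p_drop),
              nrow(x), ncol(x))
  list(out = x * m, mask = m)
}

# --- multi-head attention ----------------------------------------------------

#' Multi-head self-attention with relative position bias
#'
#' Scaled dot-product attention over the rows of `x`, with a learned
#' per-head additive bias indexed by a bucketed relative position
#' (T5 scheme). `mask[i, j] == TRUE` blocks query i from key j: its logit
#' is set to `-Inf` and its softmax weight is exactly 0. Attention rows
#' over unmasked keys sum to 1.
#'
#' @param x Input matrix `T x d_model`.
#' @param ap Attention parameter list (`Wq,bq,Wk,bk,Wv,bv,Wo,bo,bias`).
#' @param buckets 1-based `T x T` matrix of bucket indices into
#'   `ap$bias` rows.
#' @param n_heads Number of heads; `d_model` must be divisible by it.
#' @param mask Optional logical `T x T` matrix, `TRUE` = blocked.
#' @param want_cache Keep intermediates for the backward pass.
#' @return List with `out` (`T x d_model`), `attention` (list of per-head
#'   softmax weight matrices), `logits` (per-head biased logit matrices)
#'   and, if requested, `cache`.
#' @export
multi_head_attention <- function(x, ap, buckets, n_heads, mask = NULL,
                                 want_cache = FALSE) {
  Tn <- nrow(x)
  d_model <- ncol(x)
  stopifnot(d_model %% n_heads == 0L)
  dh <- d_model %/% n_heads
  if (!is.null(mask) && any(rowSums(!mask) == 0L)) {
    stop("attention mask leaves a query with no valid keys")
  }
  Q <- .addb(x %*% ap$Wq, ap$bq)
  K <- .addb(x %*% ap$Wk, ap$bk)
  V <- .addb(x %*% ap$Wv, ap$bv)
  heads <- vector("list", n_heads)
  attn <- vector("list", n_heads)
  logits <- vector("list", n_heads)
  O <- matrix(0, Tn, d_model)
  for (a in seq_len(n_heads)) {
    idx <- ((a - 1L) * dh + 1L):(a * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh) +
      matrix(ap$bias[as.vector(buckets), a], Tn, Tn)
    if (!is.null(mask)) S[mask] <- -Inf
    A <- row_softmax(S)
    O[, idx] <- A %*% V[, idx, drop = FALSE]
    attn[[a]] <- A
    logits[[a]] <- S
  }
  out <- .addb(O %*% ap$Wo, ap$bo)
  res <- list(out = out, attention = attn, logits = logits)
  if (want_cache) res$cache <- list(x = x, Q = Q, K = K, V = V, O = O,
                                    attn = attn, buckets = buckets, dh = dh)
  res
}

.mha_backward <- function(dout, cache, ap, n_heads) {
  x <- cache$x; Q <- cache$Q; K <- cache$K; V <- cache$V
  dh <- cache$dh
  Tn <- nrow(x)
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- tcrossprod(dout, ap$Wo)
  dQ <- matrix(0, Tn, ncol(Q)); dK <- dQ; dV <- dQ
  dbias <- matrix(0, nrow(ap$bias), n_heads)
  bvec <- as.vector(cache$buckets)
  for (a in seq_len(n_heads)) {
    idx <- ((a - 1L) * dh + 1L):(a * dh)
    A <- cache$attn[[a]]
    dOa <- dO[, idx, drop = FALSE]
    dA <- tcrossprod(dOa, V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(A, dOa)
    dS <- A * (dA - rowSums(A * dA))
    agg <- rowsum(as.vector(dS), bvec)
    dbias[as.integer(rownames(agg)), a] <- agg[, 1L]
    dQ[, idx] <- dS %*% K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- crossprod(dS, Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  dx <- tcrossprod(dQ, ap$Wq) + tcrossprod(dK, ap$Wk) + tcrossprod(dV, ap$Wv)
  grads <- list(Wq = crossprod(x, dQ), bq = colSums(dQ),
                Wk = crossprod(x, dK), bk = colSums(dK),
                Wv = crossprod(x, dV), bv = colSums(dV),
                Wo = dWo, bo = dbo, bias = dbias)
  list(dx = dx, grads = grads)
}

# --- full encoder stack (pre-LayerNorm residual blocks) ----------------------

.encoder_forward <- function(x, enc, buckets, n_heads, mask = NULL,
                             dropout = 0, training = FALSE,
                             keep_attention = FALSE) {
  caches <- if (training) vector("list", length(enc$layers)) else NULL
  attn_all <- if (keep_attention) vector("list", length(enc$layers)) else NULL
  logit_all <- if (keep_attention) vector("list", length(enc$layers)) else NULL
  for (l in seq_along(enc$layers)) {
    lp <- enc$layers[[l]]
    ln1 <- .ln_forward(x, lp$ln1)
    mh <- multi_head_attention(ln1$out, lp$attn, buckets, n_heads, mask,
                               want_cache = training)
    dr1 <- .dropout_forward(mh$out, dropout, training)
    x2 <- x + dr1$out
    ln2 <- .ln_forward(x2, lp$ln2)
    h1 <- .addb(ln2$out %*% lp$ffn$W1, lp$ffn$b1)
    h1r <- pmax(h1, 0)
    f <- .addb(h1r %*% lp$ffn$W2, lp$ffn$b2)
    dr2 <- .dropout_forward(f, dropout, training)
    x3 <- x2 + dr2$out
    if (training) {
      caches[[l]] <- list(ln1 = ln1, mha = mh$cache, dr1 = dr1$mask, x2 = x2,
                          ln2 = ln2, h1 = h1, h1r = h1r, dr2 = dr2$mask)
    }
    if (keep_attention) {
      attn_all[[l]] <- mh$attention
      logit_all[[l]] <- mh$logits
    }
    x <- x3
  }
  lnf <- .ln_forward(x, enc$lnf)
  list(out = lnf$out,
       cache = if (training) list(layers = caches, lnf = lnf, x_pre = x),
       attention = attn_all, logits = logit_all)
}

.encoder_backward <- function(dout, cache, enc, n_heads) {
  lb <- .ln_backward(dout, cache$lnf, enc$lnf)
  grads <- list(layers = vector("list", length(enc$layers)),
                lnf = list(g = lb$dg, b = lb$db))
  dx <- lb$dx
  for (l in rev(seq_along(enc$layers))) {
    lp <- enc$layers[[l]]
    cc <- cache$layers[[l]]
    # x3 = x2 + dropout(f)
    df <- if (is.null(cc$dr2)) dx else dx * cc$dr2
    db2 <- colSums(df)
    dW2 <- crossprod(cc$h1r, df)
    dh1r <- tcrossprod(df, lp$ffn$W2)
    dh1 <- dh1r * (cc$h1 > 0)
    db1 <- colSums(dh1)
    dW1 <- crossprod(cc$ln2$out, dh1)
    dln2_out <- tcrossprod(dh1, lp$ffn$W1)
    l2 <- .ln_backward(dln2_out, cc$ln2, lp$ln2)
    dx2 <- dx + l2$dx
    # x2 = x + dropout(attn_out)
    dattn <- if (is.null(cc$dr1)) dx2 else dx2 * cc$dr1
    mb <- .mha_backward(dattn, cc$mha, lp$attn, n_heads)
    l1 <- .ln_backward(mb$dx, cc$ln1, lp$ln1)
    dx <- dx2 + l1$dx
    grads$layers[[l]] <- list(
      ln1 = list(g = l1$dg, b = l1$db),
      attn = mb$grads,
      ln2 = list(g = l2$dg, b = l2$db),
      ffn = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
  }
  list(dx = dx, grads = grads)
}

# --- generic parameter-tree utilities ---------------------------------------

.tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- .tree_map(f, a[[i]], if (!is.null(b)) b[[i]])
    }
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

.tree_zero <- function(a) .tree_map(function(x) x * 0, a)

.tree_add <- function(a, b) .tree_map(`+`, a, b)

.tree_scale <- function(a, s) .tree_map(function(x) x * s, a)

.tree_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, .tree_flatten), use.names = FALSE)
  else as.numeric(a)
}

.tree_sq_norm <- function(a) sum(.tree_flatten(a)^2)
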