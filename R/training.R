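#' Training configuration
#'
#' Optimisation schedule: AdamW with linear learning-rate warmup from 0
#' to `peak_lr` over `warmup_steps`, then linear decay to `final_lr` at
#' `total_steps`; gradient L2-norm clipping; dropout during training.
#' The reference schedule is batch size 8 for 50,000 steps with 5,000
#' warmup steps, peak 1e-3, final 1e-8, clip norm 1.0, dropout 0.1; the
#' desk preset scales steps and warmup by the same ratio.
#'
#' @param batch_size Contexts per optimisation step (default 8).
#' @param total_steps Total optimisation steps (default 50,000).
#' @param warmup_steps Warmup steps (default 5,000; must be `< total_steps`).
#' @param peak_lr Peak learning rate (default 1e-3).
#' @param final_lr Final learning rate (default 1e-8; `< peak_lr`, `> 0`).
#' @param grad_clip_norm Global gradient L2-norm ceiling (default 1.0).
#' @param weight_decay Decoupled AdamW weight decay (default 0.01).
#' @param beta1,beta2,eps Adam moment parameters (defaults 0.9, 0.999, 1e-8).
#' @param seed RNG seed controlling initialisation, shuffling and dropout.
#' @param joint Backpropagate into the element encoder (`TRUE`) or train
#'   the regulation encoder on frozen element embeddings (`FALSE`).
#' @param target `"log1p"` trains the rate against log1p expression
#'   (matching the preprocessing of real RNA-seq targets); `"count"`
#'   trains against raw counts when available.
#' @param holdout_fraction Fraction of genes held out for validation
#'   when no chromosome split is supplied (default 0.2).
#' @param eval_every Validation interval in steps (default 100).
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, total_steps = 50000L,
                         warmup_steps = 5000L, peak_lr = 1e-3,
                         final_lr = 1e-8, grad_clip_norm = 1.0,
                         weight_decay = 0.01, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, seed = 1L, joint = TRUE,
                         target = c("log1p", "count"),
                         holdout_fraction = 0.2, eval_every = 100L) {
  stopifnot(warmup_steps < total_steps, peak_lr > final_lr, final_lr > 0,
            batch_size >= 1L, grad_clip_norm > 0)
  target <- match.arg(target)
  structure(as.list(environment()), class = "train_config")
}

#' Desk-scale training preset
#'
#' 2,000 steps with warmup scaled by the same 1/25 ratio as the step
#' count (200 steps); the element encoder is frozen at its random
#' initialisation and only the regulation encoder and prediction head
#' are trained, which keeps a full run to minutes on one CPU while
#' leaving every architectural component in place.
#'
#' @param ... Overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
train_config_desk <- function(...) {
  args <- list(total_steps = 2000L, warmup_steps = 200L, joint = FALSE)
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}

#' Learning rate at a step
#'
#' Piecewise-linear: 0 at step 0, `peak_lr` at `warmup_steps`, then
#' linear decay to `final_lr` at `total_steps`.
#'
#' @param step Step in `[0, total_steps]`.
#' @param config A [train_config()].
#' @return Learning rate (a single number).
#' @export
lr_at_step <- function(step, config) {
  if (any(step < 0 | step > config$total_steps)) {
    stop("step out of range [0, ", config$total_steps, "]")
  }
  ifelse(step < config$warmup_steps,
         config$peak_lr * step / config$warmup_steps,
         config$peak_lr + (config$final_lr - config$peak_lr) *
           (step - config$warmup_steps) /
           (config$total_steps - config$warmup_steps))
}

#' Partition genes by chromosome
#'
#' @param genes Gene data frame with a `chrom` column.
#' @param spec List with `val` and `test` chromosome vectors and
#'   optionally `train`; when `train` is omitted it is every remaining
#'   chromosome. A gene on a chromosome assigned to no partition is an
#'   error.
#' @return List of three data frames `train`, `val`, `test`.
#' @export
split_by_chromosome <- function(genes, spec) {
  val <- spec$val %||% character()
  test <- spec$test %||% character()
  train <- spec$train %||% setdiff(unique(genes$chrom), c(val, test))
  if (length(intersect(train, c(val, test))) || length(intersect(val, test))) {
    stop("chromosome partitions must be disjoint")
  }
  unassigned <- setdiff(unique(genes$chrom), c(train, val, test))
  if (length(unassigned)) {
    stop("chromosome(s) not assigned to any partition: ",
         paste(unassigned, collapse = ", "))
  }
  list(train = genes[genes$chrom %in% train, , drop = FALSE],
       val = genes[genes$chrom %in% val, , drop = FALSE],
       test = genes[genes$chrom %in% test, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a training dataset from a simulated landscape
#'
#' Pads all elements to the model length, builds one gene context per
#' gene and splits genes into train/validation sets — by chromosome when
#' `split` is given, otherwise by a seeded random gene holdout (the
#' generator emits a single chromosome, so a chromosome-level split is
#' only meaningful for multi-chromosome gene tables).
#'
#' @param sim A `sim_genome` (or any list with `elements`, `genes`,
#'   `schema`).
#' @param max_per_side Context truncation (default 200 per side).
#' @param max_distance Candidate window radius around the TSS in bp
#'   (default 1 Mb).
#' @param element_len Padded element length (default 350).
#' @param split Optional chromosome split spec for
#'   [split_by_chromosome()].
#' @param holdout_fraction Validation fraction for the random holdout.
#' @param seed Seed for the random holdout.
#' @return List of class `attnreg_dataset` with `contexts`, `targets`
#'   (log1p expression), `counts`, `elements` (padded), `genes`, and
#'   index vectors `train_idx`, `val_idx` (genes whose context is empty
#'   are excluded from both).
#' @export
make_dataset <- function(sim, max_per_side = 200L, max_distance = 1000000L,
                         element_len = 350L, split = NULL,
                         holdout_fraction = 0.2, seed = 1L) {
  elements <- lapply(sim$elements, pad_element, target_len = element_len)
  genes <- sim$genes
  contexts <- lapply(seq_len(nrow(genes)), function(i) {
    build_gene_context(genes[i, ], elements, max_per_side = max_per_side,
                       max_distance = max_distance)
  })
  usable <- which(vapply(contexts, function(cc) length(cc$elements) > 0L, TRUE))
  if (!is.null(split)) {
    sp <- split_by_chromosome(genes, split)
    train_idx <- intersect(which(genes$gene_id %in% sp$train$gene_id), usable)
    val_idx <- intersect(which(genes$gene_id %in% sp$val$gene_id), usable)
  } else {
    set.seed(seed)
    n_val <- max(1L, round(holdout_fraction * length(usable)))
    val_idx <- sort(sample(usable, n_val))
    train_idx <- setdiff(usable, val_idx)
  }
  structure(list(contexts = contexts, targets = genes$expression,
                 counts = genes$count %||% rep(NA_real_, nrow(genes)),
                 elements = elements, genes = genes, schema = sim$schema,
                 element_len = as.integer(element_len),
                 train_idx = train_idx, val_idx = val_idx),
            class = "attnreg_dataset")
}

# --- AdamW -------------------------------------------------------------------

.adamw_step <- function(p, g, m, v, t, lr, cfg) {
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    for (i in seq_along(p)) {
      r <- .adamw_step(p[[i]], g[[i]], m[[i]], v[[i]], t, lr, cfg)
      out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
    }
    return(list(p = out_p, m = out_m, v = out_v))
  }
  m2 <- cfg$beta1 * m + (1 - cfg$beta1) * g
  v2 <- cfg$beta2 * v + (1 - cfg$beta2) * g * g
  mh <- m2 / (1 - cfg$beta1^t)
  vh <- v2 / (1 - cfg$beta2^t)
  list(p = p - lr * (mh / (sqrt(vh) + cfg$eps) + cfg$weight_decay * p),
       m = m2, v = v2)
}

#' Clip a gradient tree by global L2 norm
#'
#' @param grads Nested list of gradient arrays.
#' @param max_norm Norm ceiling.
#' @return List with `grads` (rescaled if needed) and `norm` (pre-clip).
#' @export
clip_gradients <- function(grads, max_norm) {
  nrm <- sqrt(.tree_sq_norm(grads))
  if (is.finite(nrm) && nrm > max_norm) {
    grads <- .tree_scale(grads, max_norm / nrm)
  }
  list(grads = grads, norm = nrm)
}

.dataset_target <- function(dataset, config) {
  if (config$target == "count") {
    if (anyNA(dataset$counts)) stop("count targets requested but unavailable")
    dataset$counts
  } else dataset$targets
}

#' Train the expression model
#'
#' Minimises the Poisson negative log-likelihood of observed expression
#' with AdamW under the warmup/decay schedule, gradient clipping and
#' dropout. With `config$joint = FALSE` the element encoder stays at its
#' (seeded) random initialisation and all element embeddings are
#' precomputed once, so each step only updates the regulation encoder
#' and prediction head. The checkpoint with the best validation Pearson
#' r is retained. Identical seeds give identical loss trajectories.
#'
#' @param dataset An [make_dataset()] result.
#' @param model An [attnreg_model()]; when `NULL` one is created from
#'   `d_model` with the dataset's track schema.
#' @param config A [train_config()].
#' @param d_model Width used when `model` is `NULL` (default 64, the
#'   desk-scale variant).
#' @param verbose Print progress every `eval_every` steps.
#' @return List of class `attnreg_fit`: `model` (best-validation
#'   weights), `final_model`, `metrics` (data frame step/lr/loss),
#'   `val_metrics` (step, pearson_r), `best_val_r`, `element_embs`.
#' @export
train <- function(dataset, model = NULL, config = train_config(),
                  d_model = 64L, verbose = FALSE) {
  set.seed(config$seed)
  if (is.null(model)) {
    ec <- element_encoder_config(d_model = d_model, d_ff = 4L * d_model,
                                 element_len = dataset$element_len %||% 350L)
    rc <- regulation_encoder_config(d_model = d_model, d_ff = 4L * d_model)
    model <- attnreg_model(ec, rc, dataset$schema)
  }
  y_all <- .dataset_target(dataset, config)
  tr <- dataset$train_idx
  if (length(tr) == 0L) stop("empty training set")

  element_embs <- NULL
  if (!config$joint) {
    element_embs <- encode_elements(dataset$elements, model$element)
  }

  opt_state <- NULL
  loss_log <- numeric(config$total_steps)
  lr_log <- numeric(config$total_steps)
  val_steps <- integer(); val_r <- numeric()
  best <- list(r = -Inf, model = model)
  order_idx <- sample(tr)
  ptr <- 1L

  for (step in seq_len(config$total_steps)) {
    batch <- integer(config$batch_size)
    for (b in seq_len(config$batch_size)) {
      if (ptr > length(order_idx)) { order_idx <- sample(tr); ptr <- 1L }
      batch[b] <- order_idx[ptr]; ptr <- ptr + 1L
    }
    grads <- NULL
    loss <- 0
    B <- length(batch)
    for (i in batch) {
      fwd <- .forward_context_impl(model, dataset$contexts[[i]],
                                   element_embs = element_embs,
                                   training = TRUE)
      lam <- fwd$lambda
      yi <- y_all[i]
      loss <- loss + (lam - yi * log(lam)) / B
      d_lambda <- (1 - yi / lam) / B
      g <- .backward_context(model, fwd, d_lambda, joint = config$joint)
      g <- if (config$joint) list(element = g$element, regulation = g$regulation)
           else list(regulation = g$regulation)
      grads <- if (is.null(grads)) g else .tree_add(grads, g)
    }
    if (!is.finite(loss)) {
      stop("non-finite loss at step ", step,
           " (lambda range ", paste(range(fwd$lambda), collapse = ".."), ")")
    }
    grads <- clip_gradients(grads, config$grad_clip_norm)$grads
    lr <- lr_at_step(step, config)
    params <- if (config$joint) {
      list(element = model$element$params, regulation = model$regulation$params)
    } else list(regulation = model$regulation$params)
    if (is.null(opt_state)) {
      opt_state <- list(m = .tree_zero(grads), v = .tree_zero(grads))
    }
    upd <- .adamw_step(params, grads, opt_state$m, opt_state$v, step, lr, config)
    opt_state$m <- upd$m; opt_state$v <- upd$v
    if (config$joint) {
      model$element$params <- upd$p$element
      model$regulation$params <- upd$p$regulation
    } else {
      model$regulation$params <- upd$p$regulation
    }
    loss_log[step] <- loss
    lr_log[step] <- lr

    if (step %% config$eval_every == 0L || step == config$total_steps) {
      ee <- if (config$joint) encode_elements(dataset$elements, model$element)
            else element_embs
      r <- .val_pearson(model, dataset, y_all, ee)
      val_steps <- c(val_steps, step); val_r <- c(val_r, r)
      if (is.finite(r) && r > best$r) best <- list(r = r, model = model)
      if (verbose) {
        message(sprintf("step %d  lr %.2e  loss %.4f  val r %.3f",
                        step, lr, loss, r))
      }
    }
  }
  metrics <- data.frame(step = seq_len(config$total_steps), lr = lr_log,
                        loss = loss_log)
  val_log <- data.frame(step = val_steps, pearson_r = val_r)
  structure(list(model = best$model, final_model = model, metrics = metrics,
                 val_metrics = val_log, best_val_r = best$r,
                 element_embs = element_embs, config = config),
            class = "attnreg_fit")
}

.val_pearson <- function(model, dataset, y_all, element_embs) {
  idx <- dataset$val_idx
  if (length(idx) < 2L) return(NA_real_)
  pred <- vapply(idx, function(i) {
    forward_context(model, dataset$contexts[[i]], element_embs)$lambda
  }, 0)
  if (stats::sd(pred) == 0 || stats::sd(y_all[idx]) == 0) return(NA_real_)
  stats::cor(pred, y_all[idx])
}

#' Predict expression for a set of contexts
#'
#' @param model An [attnreg_model()].
#' @param dataset An `attnreg_dataset`.
#' @param idx Gene indices (default all).
#' @param element_embs Optional precomputed element embeddings.
#' @return Data frame `gene_id`, `chrom`, `predicted`, `observed`.
#' @export
predict_genes <- function(model, dataset, idx = seq_along(dataset$contexts),
                          element_embs = NULL) {
  if (is.null(element_embs)) {
    element_embs <- encode_elements(dataset$elements, model$element)
  }
  pred <- vapply(idx, function(i) {
    forward_context(model, dataset$contexts[[i]], element_embs)$lambda
  }, 0)
  data.frame(gene_id = dataset$genes$gene_id[idx],
             chrom = dataset$genes$chrom[idx],
             predicted = pred, observed = dataset$targets[idx],
             stringsAsFactors = FALSE)
}

#' Per-chromosome evaluation of expression predictions
#'
#' Pearson r and RMSE between observed and predicted expression for each
#' chromosome group; groups with fewer than 3 genes are skipped with a
#' warning, and zero-variance predictions give `NaN` with a warning.
#'
#' @param predictions Data frame with `chrom`, `predicted`, `observed`
#'   (as from [predict_genes()]).
#' @return Data frame `chrom`, `n`, `pearson_r`, `rmse`.
#' @export
evaluate_expression <- function(predictions) {
  out <- lapply(split(predictions, predictions$chrom), function(d) {
    if (nrow(d) < 3L) {
      warning("chromosome ", d$chrom[1L], " has fewer than 3 genes; skipped")
      return(NULL)
    }
    r <- if (stats::sd(d$predicted) == 0 || stats::sd(d$observed) == 0) {
      warning("zero-variance predictions on ", d$chrom[1L])
      NaN
    } else stats::cor(d$predicted, d$observed)
    data.frame(chrom = d$chrom[1L], n = nrow(d), pearson_r = r,
               rmse = sqrt(mean((d$predicted - d$observed)^2)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Repeat training over several seeds
#'
#' Robustness helper: trains once per seed and reports the mean and SD
#' of the best validation Pearson r.
#'
#' @param dataset An `attnreg_dataset`.
#' @param config A [train_config()]; its seed is replaced by
#'   `seed + 0 .. n_repeats - 1`.
#' @param n_repeats Number of seeds (default 5).
#' @param ... Passed to [train()].
#' @return List with `runs` (list of fits), `val_r` (vector), `mean_r`,
#'   `sd_r`.
#' @export
train_repeated <- function(dataset, config, n_repeats = 5L, ...) {
  runs <- lapply(seq_len(n_repeats) - 1L, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    train(dataset, config = cfg, ...)
  })
  vr <- vapply(runs, `[[`, 0, "best_val_r")
  list(runs = runs, val_r = vr, mean_r = mean(vr), sd_r = stats::sd(vr))
}
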