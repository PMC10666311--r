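test_that("learning-rate schedule is the specified warmup/decay ramp", {
  cfg <- train_config(total_steps = 50000L, warmup_steps = 5000L)
  expect_equal(lr_at_step(0L, cfg), 0)
  expect_equal(lr_at_step(5000L, cfg), 1e-3)
  expect_equal(lr_at_step(50000L, cfg), 1e-8)
  # midpoint of the decay segment
  expect_equal(lr_at_step((5000L + 50000L) / 2, cfg), (1e-3 + 1e-8) / 2)
  # piecewise linear, continuous, maximum at the warmup end
  lrs <- lr_at_step(0:50000, cfg)
  expect_equal(max(lrs), 1e-3)
  expect_equal(which.max(lrs) - 1L, 5000L)
  expect_lt(max(abs(diff(lrs, differences = 2))), 1e-6)
  expect_error(lr_at_step(-1L, cfg), "out of range")
  expect_error(lr_at_step(50001L, cfg), "out of range")
})

test_that("train_config validates the schedule shape", {
  expect_error(train_config(total_steps = 100L, warmup_steps = 100L))
  expect_error(train_config(peak_lr = 1e-8, final_lr = 1e-3))
  cfg <- train_config_desk()
  expect_equal(cfg$total_steps, 2000L)
  expect_equal(cfg$warmup_steps, 200L)   # scaled by the same 1/25 ratio
  expect_false(cfg$joint)
})

test_that("split_by_chromosome partitions genes and flags strays", {
  genes <- data.frame(gene_id = paste0("G", 1:9),
                      chrom = rep(c("c1", "c2", "c3"), each = 3))
  sp <- split_by_chromosome(genes, list(val = "c2", test = "c3"))
  expect_equal(nrow(sp$train) + nrow(sp$val) + nrow(sp$test), 9L)
  expect_setequal(sp$val$gene_id, paste0("G", 4:6))
  expect_equal(nrow(split_by_chromosome(genes,
                                        list(val = "c2", test = character(),
                                             train = c("c1", "c3")))$test), 0L)
  expect_error(split_by_chromosome(genes, list(val = "c2", test = "c3",
                                               train = "c9")),
               "not assigned")
  expect_error(split_by_chromosome(genes, list(val = "c1", test = "c1")),
               "disjoint")
})

test_that("gradient clipping rescales to the ceiling norm", {
  g <- list(a = matrix(c(6, 8), 1), b = list(c = 0))  # norm 10
  cl <- clip_gradients(g, 1.0)
  expect_equal(cl$norm, 10)
  expect_equal(sqrt(attnreg:::.tree_sq_norm(cl$grads)), 1.0, tolerance = 1e-6)
  # below the ceiling: untouched
  cl2 <- clip_gradients(g, 20)
  expect_identical(cl2$grads, g)
})

small_sim_dataset <- function(seed = 70L, n_genes = 20L) {
  sim <- simulate_genome(sim_config(
    seed = seed, chrom_len = 2000000L, n_genes = n_genes, n_elements = 60L,
    element_len = 30L, regulators_per_gene = 3L, max_link_distance = 500000L,
    effect_scale = 12, baseline_rate = 4, noise_sd = 0.1, n_tads = 3L))
  make_dataset(sim, element_len = 30L, seed = seed + 1L)
}

test_that("short training reduces the loss on a small synthetic set", {
  ds <- small_sim_dataset()
  cfg <- train_config_desk(total_steps = 200L, warmup_steps = 20L,
                           seed = 71L, eval_every = 50L)
  fit <- train(ds, config = cfg, d_model = 16L)
  first <- mean(fit$metrics$loss[1:10])
  last <- mean(tail(fit$metrics$loss, 10))
  expect_lt(last, first)
  expect_s3_class(fit$metrics, "data.frame")
  expect_true(all(c("step", "lr", "loss") %in% names(fit$metrics)))
})

test_that("identical seeds give identical losses and checkpoints", {
  ds <- small_sim_dataset(seed = 72L, n_genes = 10L)
  cfg <- train_config_desk(total_steps = 10L, warmup_steps = 2L, seed = 73L,
                           eval_every = 5L)
  f1 <- train(ds, config = cfg, d_model = 16L)
  f2 <- train(ds, config = cfg, d_model = 16L)
  expect_identical(f1$metrics$loss[10], f2$metrics$loss[10])
  expect_identical(f1$metrics$loss, f2$metrics$loss)
  expect_identical(f1$final_model$regulation$params,
                   f2$final_model$regulation$params)
})

test_that("joint training reaches the element encoder deterministically", {
  ds <- small_sim_dataset(seed = 74L, n_genes = 6L)
  cfg <- train_config(total_steps = 4L, warmup_steps = 1L, batch_size = 2L,
                      seed = 75L, joint = TRUE, eval_every = 4L)
  f1 <- train(ds, config = cfg, d_model = 8L)
  f2 <- train(ds, config = cfg, d_model = 8L)
  expect_identical(f1$metrics$loss, f2$metrics$loss)
  # element parameters moved away from their initialisation
  set.seed(cfg$seed)
  ec <- element_encoder_config(d_model = 8L, d_ff = 32L, element_len = 30L)
  rc <- regulation_encoder_config(d_model = 8L, d_ff = 32L)
  init <- attnreg_model(ec, rc, ds$schema)
  expect_gt(max(abs(f1$final_model$element$params$W_sig -
                      init$element$params$W_sig)), 0)
})

test_that("checkpoints round-trip through disk", {
  model <- tiny_model(seed = 76L)
  p <- tempfile(fileext = ".rds")
  save_checkpoint(model, p, meta = list(step = 3L))
  ck <- load_checkpoint(p)
  expect_equal(ck$meta$step, 3L)
  set.seed(77)
  E <- matrix(rnorm(3 * 16), 3, 16); rownames(E) <- paste0("E", 1:3)
  o1 <- regulation_forward(model$regulation, E, c(1e3L, 5e4L, 2e5L), 1e5L)
  o2 <- regulation_forward(ck$model$regulation, E, c(1e3L, 5e4L, 2e5L), 1e5L)
  expect_identical(o1$gene_out, o2$gene_out)
})

test_that("evaluate_expression reports per-chromosome r and RMSE", {
  preds <- data.frame(chrom = rep("cA", 4), predicted = c(1, 2, 3, 4),
                      observed = c(1, 2, 3, 4))
  ev <- evaluate_expression(preds)
  expect_equal(ev$pearson_r, 1.0)
  expect_equal(ev$rmse, 0)
  preds$predicted <- -preds$observed + 10
  expect_equal(evaluate_expression(preds)$pearson_r, -1.0)
  # hand-computed 4-point Pearson r
  x <- c(1, 2, 4, 7); y <- c(2, 1, 5, 6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  ev3 <- evaluate_expression(data.frame(chrom = "cA", predicted = x,
                                        observed = y))
  expect_equal(ev3$pearson_r, r_hand)
  # undersized groups are skipped with a warning
  expect_warning(
    ev4 <- evaluate_expression(data.frame(chrom = c("cA", "cA", "cA", "cB"),
                                          predicted = c(x[1:3], 1),
                                          observed = c(y[1:3], 2))),
    "fewer than 3")
  expect_equal(ev4$chrom, "cA")
  # zero-variance predictions give NaN with a warning
  expect_warning(
    ev5 <- evaluate_expression(data.frame(chrom = rep("cA", 4),
                                          predicted = rep(1, 4),
                                          observed = y)),
    "zero-variance")
  expect_true(is.nan(ev5$pearson_r))
})
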