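# small scaled dataset + split for engine-level protocol tests
proto_fixture <- function(seed = 42) {
  ds <- scale_unit_interval(generate_task(separable_task(seed = seed)))
  list(ds = ds, split = stratified_split(ds$labels, seed = seed))
}

test_that("training a separable binary task reaches high validation accuracy", {
  fx <- proto_fixture()
  arch <- tiny_arch(n_classes = 2)
  cfg <- train_config(max_epochs = 30, batch_size = 16, lr = 1e-3,
                      patience = 30, seed = 1)
  fit <- train(init_parameters(arch, seed = 1), fx$ds, fx$split, cfg)
  expect_gte(max(fit$history$val_acc), 0.95)
  expect_gte(evaluate(fit$model, fx$ds, fx$split$test)$accuracy, 0.9)
  expect_equal(names(fit$history),
               c("epoch", "train_loss", "train_acc", "val_acc"))
})

test_that("training is deterministic for fixed seeds", {
  fx <- proto_fixture()
  arch <- tiny_arch(n_classes = 2)
  cfg <- train_config(max_epochs = 4, batch_size = 16, lr = 1e-3, seed = 9)
  f1 <- train(init_parameters(arch, seed = 3), fx$ds, fx$split, cfg)
  f2 <- train(init_parameters(arch, seed = 3), fx$ds, fx$split, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("frozen parameters are bitwise unchanged by training, in every mode", {
  fx <- proto_fixture()
  arch <- tiny_arch(n_classes = 2)
  cfg <- train_config(max_epochs = 2, batch_size = 16, lr = 1e-3, seed = 2)
  base <- init_parameters(arch, seed = 5)
  widx <- spectracnn:::.weight_layer_indices(arch)
  conv_idx <- widx[widx <= arch$representation_end]

  for (mode in c("train_all", "fine_tune", "freeze_all_conv",
                 "freeze_all_conv_but_last")) {
    m <- set_representation_mode(base, mode)
    fit <- train(m, fx$ds, fx$split, cfg)
    frozen <- widx[!m$trainable[widx]]
    for (i in frozen)
      expect_identical(fit$model$params[[i]], base$params[[i]])
    if (mode %in% c("train_all", "fine_tune"))
      expect_false(identical(fit$model$params[[conv_idx[1]]],
                             base$params[[conv_idx[1]]]))
  }

  # fully frozen model: returned parameters identical to the input
  m <- set_representation_mode(base, "freeze_all_conv")
  m$trainable[] <- FALSE
  fit <- train(m, fx$ds, fx$split, cfg)
  expect_identical(fit$model$params, base$params)
})

test_that("representation modes set trainable flags as specified", {
  arch <- build_architecture("variant_lenet", 2000, 2)
  m <- init_parameters(arch, seed = 1)
  widx <- spectracnn:::.weight_layer_indices(arch)
  conv_idx <- widx[widx <= arch$representation_end]
  expect_length(conv_idx, 3)

  m1 <- set_representation_mode(m, "train_all")
  expect_true(all(m1$trainable[widx]))
  m2 <- set_representation_mode(m, "freeze_all_conv")
  expect_true(all(!m2$trainable[conv_idx]))
  expect_true(all(m2$trainable[setdiff(widx, conv_idx)]))
  m3 <- set_representation_mode(m, "freeze_all_conv_but_last")
  expect_equal(sum(m3$trainable[conv_idx]), 1)
  expect_true(m3$trainable[conv_idx[3]])
})

test_that("head replacement keeps the representation bitwise and resizes the output", {
  arch <- tiny_arch(n_classes = 2)
  m <- init_parameters(arch, seed = 4)
  widx <- spectracnn:::.weight_layer_indices(arch)
  conv_idx <- widx[widx <= arch$representation_end]
  dense_idx <- setdiff(widx, conv_idx)

  m12 <- replace_decision_head(m, 12, seed = 8)
  for (i in conv_idx)
    expect_identical(m12$params[[i]], m$params[[i]])
  out <- m12$params[[length(arch$layers)]]
  expect_equal(ncol(out$W), 12)
  expect_equal(m12$architecture$head_activation, "softmax")

  m2 <- replace_decision_head(m, 2, seed = 9)
  expect_equal(m2$architecture$head_activation, "sigmoid")
  expect_equal(ncol(m2$params[[length(arch$layers)]]$W), 1)
  expect_false(identical(m2$params[[dense_idx[1]]]$W, m$params[[dense_idx[1]]]$W))

  m3 <- replace_decision_head(m, 3, seed = 9)
  expect_equal(m3$architecture$head_activation, "softmax")
  expect_error(replace_decision_head(m, 1), "n_classes")
})

test_that("metrics follow the confusion-matrix identities", {
  met <- classification_metrics(c(1, 1, 2), c(1, 1, 2), n_classes = 2)
  expect_equal(met$accuracy, 1)
  expect_equal(unname(met$sensitivity), c(1, 1))
  expect_true(all(diag(met$confusion) == c(2, 1)))

  # binary all-positive predictor: sensitivity 1 / specificity 0 for the
  # positive class
  truth <- rep(c(1, 2), each = 5)
  pred <- rep(2, 10)
  met <- classification_metrics(truth, pred, n_classes = 2)
  expect_equal(unname(met$sensitivity[2]), 1)
  expect_equal(unname(met$specificity[2]), 0)
  expect_equal(unname(met$sensitivity[1]), 0)

  # hand-computed 2-class table [[8,2],[1,9]]
  truth <- rep(c(1, 2), c(10, 10))
  pred <- c(rep(1, 8), rep(2, 2), rep(1, 1), rep(2, 9))
  met <- classification_metrics(truth, pred, n_classes = 2)
  expect_equal(met$accuracy, 0.85)
  expect_equal(unname(met$sensitivity), c(0.8, 0.9))
  expect_equal(unname(met$specificity), c(0.9, 0.8))
  expect_equal(rowSums(met$confusion), c(truth = 10, truth = 10),
               ignore_attr = TRUE)
})

test_that("three-class metrics match a hand-computed table", {
  # confusion (rows truth): [[5,1,0],[2,6,2],[0,1,3]]
  truth <- rep(1:3, c(6, 10, 4))
  pred <- c(rep(1, 5), 2,
            rep(1, 2), rep(2, 6), rep(3, 2),
            2, rep(3, 3))
  met <- classification_metrics(truth, pred, n_classes = 3)
  expect_equal(met$accuracy, 14 / 20)
  expect_equal(unname(met$sensitivity), c(5 / 6, 6 / 10, 3 / 4))
  expect_equal(unname(met$specificity), c(12 / 14, 8 / 10, 14 / 16))
})

test_that("the Welch comparison behaves at the edges and matches the closed form", {
  a <- rep(0.9, 10)
  expect_equal(compare_ttest(a, a), 1.0)
  set.seed(3)
  x <- 0.99 + rnorm(10, 0, 1e-3)
  y <- 0.50 + rnorm(10, 0, 1e-3)
  expect_lt(compare_ttest(x, y), 1e-3)
  expect_equal(compare_ttest(x, y), compare_ttest(y, x))

  tstat <- (mean(x) - mean(y)) / sqrt(var(x) / 10 + var(y) / 10)
  df <- (var(x) / 10 + var(y) / 10)^2 /
    ((var(x) / 10)^2 / 9 + (var(y) / 10)^2 / 9)
  p_closed <- 2 * pt(-abs(tstat), df)
  expect_equal(compare_ttest(x, y), p_closed, tolerance = 1e-12)
  expect_error(compare_ttest(0.5, c(0.4, 0.6)), "length")
})

test_that("protocol presets expand to the documented step sequences", {
  fam <- list(source = "src", targets = list("t12", "t5", "t2"))
  tr <- protocol_preset("TRANSFER", fam)
  expect_length(tr, 2)
  expect_equal(vapply(tr, `[[`, "", "mode"), c("train_all", "freeze_all_conv"))
  sb <- protocol_preset("SCENARIO_B", fam)
  expect_length(sb, 4)
  expect_equal(sb[[length(sb)]]$mode, "freeze_all_conv_but_last")
  expect_equal(sb[[2]]$dataset, "t2")
  expect_equal(sb[[3]]$dataset, "t5")
  sa <- protocol_preset("SCENARIO_A", fam)
  expect_equal(vapply(sa, `[[`, "", "mode"),
               c("train_all", "fine_tune", "freeze_all_conv"))
  expect_length(protocol_preset("SCRATCH", fam), 1)
})

test_that("run_protocol threads the representation and evaluates every step", {
  grid <- bin_grid(100, 160, 0.1)
  src <- task_spec(grid, n_per_class = c(25, 25), noise = quiet_noise(),
                   shared_fraction = 0, n_peaks = 4, amp_range = c(0.4, 1),
                   seed = 51)
  tg <- task_spec(grid, n_per_class = c(8, 8, 8), noise = quiet_noise(),
                  shared_fraction = 0, n_peaks = 4, amp_range = c(0.4, 1),
                  seed = 52)
  fam <- generate_task_family(src, list(tg), overlap = 0.5)
  cfg <- train_config(max_epochs = 5, batch_size = 8, lr = 1e-3, seed = 1)
  steps <- list(protocol_step(fam$source, "train_all"),
                protocol_step(fam$targets[[1]], "freeze_all_conv"))
  res <- run_protocol(steps, "variant_lecun", cfg)
  expect_length(res$steps, 2)
  expect_s3_class(res$steps[[1]]$metrics, "classification_metrics")
  expect_equal(res$final_model$architecture$n_classes, 3L)
  # conv parameters of the final model come from the source step unchanged
  rep_end <- res$final_model$architecture$representation_end
  for (i in seq_len(rep_end)) {
    if (is.null(res$final_model$params[[i]])) next
    expect_identical(res$final_model$params[[i]],
                     res$steps[[1]]$model$params[[i]])
  }
  expect_error(run_protocol(list(protocol_step(fam$source, "fine_tune")),
                            "variant_lecun", cfg), "train_all")
})

test_that("experiments are reproducible and summarise their iterations", {
  grid <- bin_grid(100, 160, 0.1)
  src <- task_spec(grid, n_per_class = c(20, 20), noise = quiet_noise(),
                   shared_fraction = 0, n_peaks = 4, amp_range = c(0.4, 1),
                   seed = 61)
  tg <- task_spec(grid, n_per_class = c(10, 10), noise = quiet_noise(),
                  shared_fraction = 0, n_peaks = 4, amp_range = c(0.4, 1),
                  seed = 62)
  fam <- generate_task_family(src, list(tg, tg, tg), overlap = 0.5)
  cfg <- train_config(max_epochs = 3, batch_size = 8, lr = 1e-3, seed = 1)
  tab <- run_experiment("SCRATCH", "variant_lecun", fam, n_iterations = 2,
                        base_seed = 5, cfg = cfg)
  acc <- attr(tab, "iterations")
  expect_equal(dim(acc), c(2, 1))
  expect_equal(tab$mean_accuracy, mean(acc))
  expect_equal(tab$sd_accuracy, sd(acc))
  expect_match(tab$formatted, "\\d\\.\\d\\d \\+/- \\d\\.\\d\\d")

  tab2 <- run_experiment("SCRATCH", "variant_lecun", fam, n_iterations = 2,
                         base_seed = 5, cfg = cfg)
  expect_identical(attr(tab2, "iterations"), acc)
  expect_error(run_experiment("SCRATCH", "variant_lecun", fam,
                              n_iterations = 1), "n_iterations")
})
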