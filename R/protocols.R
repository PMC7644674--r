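#' Training configuration
#'
#' @param max_epochs Maximum number of epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience: epochs without validation-accuracy
#'   improvement before training stops. The returned model is always the
#'   checkpoint with the best validation accuracy ("saved only on
#'   improvement").
#' @param seed Integer seed driving mini-batch shuffling and dropout.
#' @param ratios Train/validation/test split ratios used by the protocol
#'   runners.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 100L, batch_size = 32L, lr = 1e-4,
                         patience = 10L, seed = 1L,
                         ratios = c(0.6, 0.2, 0.2)) {
  stopifnot(max_epochs >= 1, batch_size >= 1, lr > 0, patience >= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience), seed = as.integer(seed),
                 ratios = ratios),
            class = "train_config")
}

# Deepest layer index whose activations are constant during training: all
# weight layers at or before it are frozen and no dropout layer precedes it.
# Activations up to here are cached once instead of recomputed every batch.
.frozen_prefix_end <- function(model) {
  layers <- model$architecture$layers
  end <- 0L
  for (i in seq_along(layers)) {
    k <- layers[[i]]$kind
    if (k == "dropout") break
    if (k %in% c("conv", "dense", "output") && model$trainable[i]) break
    end <- i
  }
  end
}

# Forward through layers 1..prefix_end for all rows of `mat`, batched.
.cache_prefix <- function(model, mat, prefix_end, batch_size = 64L) {
  if (prefix_end == 0L) return(mat)
  n <- nrow(mat)
  pieces <- vector("list", ceiling(n / batch_size))
  j <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    X <- .as_input_cube(mat[idx, , drop = FALSE])
    j <- j + 1L
    pieces[[j]] <- .forward_range(model, X, 1L, prefix_end)$state
  }
  s1 <- pieces[[1]]
  if (is.matrix(s1)) {
    do.call(rbind, pieces)
  } else {
    d <- dim(s1)
    out <- array(0, dim = c(d[1], d[2], n))
    at <- 0L
    for (p in pieces) {
      np <- dim(p)[3]
      out[, , (at + 1L):(at + np)] <- p
      at <- at + np
    }
    out
  }
}

.take_rows <- function(state, idx) {
  if (is.matrix(state)) state[idx, , drop = FALSE]
  else state[, , idx, drop = FALSE]
}

#' Train a CNN model on a spectra dataset
#'
#' Minimises class-weighted cross-entropy on the training subset with Adam,
#' evaluating validation accuracy after every epoch. The parameters are
#' checkpointed only on strict validation-accuracy improvement and the best
#' checkpoint is returned; training stops early after `patience` epochs
#' without improvement. Layers flagged non-trainable (see
#' [set_representation_mode()]) are left bitwise unchanged; activations below
#' the first trainable layer are computed once and cached.
#'
#' @param model A `cnn_model` from [init_parameters()] (possibly with frozen
#'   layers).
#' @param ds A scaled [spectra_dataset()] whose bin count equals the model's
#'   `input_length`.
#' @param split A [stratified_split()] of the dataset.
#' @param cfg A [train_config()].
#' @return List with `model` (best checkpoint) and `history` (data frame of
#'   per-epoch train loss/accuracy and validation loss/accuracy).
#' @export
train <- function(model, ds, split, cfg = train_config()) {
  arch <- model$architecture
  if (ncol(ds$matrix) != arch$input_length)
    stop(sprintf("dataset has %d bins but model expects %d",
                 ncol(ds$matrix), arch$input_length))
  if (!ds$scaled)
    warning("dataset is not scaled to [0, 1]; call scale_unit_interval() first")
  if (length(ds$class_names) != arch$n_classes)
    stop(sprintf("dataset has %d classes but model head expects %d",
                 length(ds$class_names), arch$n_classes))
  tr_y <- ds$labels[split$train]
  if (length(unique(tr_y)) < arch$n_classes ||
      any(tabulate(tr_y, arch$n_classes) == 0))
    stop("every class must appear in the training subset")
  w <- class_weights(tr_y, arch$n_classes)

  layers <- arch$layers
  n_layers <- length(layers)
  widx <- .weight_layer_indices(arch)
  tidx <- widx[model$trainable[widx]]
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_acc = numeric(0))

  if (length(tidx) == 0L) {
    # nothing to train: the incoming parameters are already the checkpoint
    pred <- predict_classes(model, ds$matrix[split$validation, , drop = FALSE])
    acc <- mean(pred == ds$labels[split$validation])
    return(list(model = model,
                history = data.frame(epoch = 0L, train_loss = NA_real_,
                                     train_acc = NA_real_, val_acc = acc)))
  }

  prefix_end <- .frozen_prefix_end(model)
  from <- prefix_end + 1L
  # with no frozen prefix the "cache" is the raw matrix, sliced into cubes
  tr_state <- .cache_prefix(model, ds$matrix[split$train, , drop = FALSE],
                            prefix_end)
  val_state <- .cache_prefix(model, ds$matrix[split$validation, , drop = FALSE],
                             prefix_end)
  get_state <- function(cache, idx) {
    if (prefix_end == 0L) .as_input_cube(cache[idx, , drop = FALSE])
    else .take_rows(cache, idx)
  }
  val_y <- ds$labels[split$validation]
  val_acc_of <- function(m) {
    pred <- integer(length(val_y))
    n <- length(val_y)
    for (start in seq(1L, n, by = 64L)) {
      idx <- start:min(start + 63L, n)
      logits <- .forward_range(m, get_state(val_state, idx), from, n_layers)$state
      P <- .head_probabilities(logits, arch$head_activation)
      if (arch$head_activation == "sigmoid") P <- cbind(1 - P[, 1], P[, 1])
      pred[idx] <- max.col(P, ties.method = "first")
    }
    mean(pred == val_y)
  }

  n_tr <- length(split$train)
  adam <- .adam_init(model, tidx)
  best <- list(params = model$params, acc = -Inf, epoch = 0L)
  stall <- 0L

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(n_tr)
      ep_loss <- 0; ep_hits <- 0L
      for (start in seq(1L, n_tr, by = cfg$batch_size)) {
        bidx <- ord[start:min(start + cfg$batch_size - 1L, n_tr)]
        fw <- .forward_range(model, get_state(tr_state, bidx), from, n_layers,
                             train = TRUE)
        y <- tr_y[bidx]
        lg <- .loss_and_grad(fw$state, y, w, arch$head_activation)
        P <- .head_probabilities(fw$state, arch$head_activation)
        if (arch$head_activation == "sigmoid") P <- cbind(1 - P[, 1], P[, 1])
        ep_hits <- ep_hits + sum(max.col(P, ties.method = "first") == y)
        ep_loss <- ep_loss + lg$loss * length(bidx)
        grads <- .backward_range(model, fw$caches, lg$grad, min(tidx), n_layers)
        upd <- .adam_step(model, grads, adam, tidx, cfg$lr)
        model <- upd$model
        adam <- upd$state
      }
      vacc <- val_acc_of(model)
      history[nrow(history) + 1L, ] <- list(epoch, ep_loss / n_tr,
                                            ep_hits / n_tr, vacc)
      if (vacc > best$acc) {
        best <- list(params = model$params, acc = vacc, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  })
  model$params <- best$params
  list(model = model, history = history)
}

#' Replace the decision head of a model
#'
#' Keeps the representation (convolution/pooling) parameters bitwise intact,
#' re-initialises every fully connected layer, and rebuilds the output layer
#' for `n_classes` (sigmoid head for binary, softmax otherwise). Used when a
#' representation trained on one task is carried to a new task.
#'
#' @param model A `cnn_model`.
#' @param n_classes Class count of the new task (>= 2).
#' @param seed Seed for the re-initialised decision parameters.
#' @return The model with a fresh decision portion (all layers trainable).
#' @export
replace_decision_head <- function(model, n_classes, seed = 1L) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  arch <- model$architecture
  head_activation <- if (n_classes == 2L) "sigmoid" else "softmax"
  out_units <- if (head_activation == "sigmoid") 1L else as.integer(n_classes)
  out_idx <- length(arch$layers)
  stopifnot(arch$layers[[out_idx]]$kind == "output")
  arch$layers[[out_idx]]$units <- out_units
  arch$layers[[out_idx]]$activation <- head_activation
  arch$n_classes <- as.integer(n_classes)
  arch$head_activation <- head_activation
  model$architecture <- arch
  with_seed(seed, {
    for (i in seq_along(arch$layers)) {
      if (i <= arch$representation_end) next
      l <- arch$layers[[i]]
      if (l$kind %in% c("dense", "output")) {
        fan_in <- l$in_features
        units <- if (l$kind == "dense") l$units else out_units
        model$params[[i]] <- list(
          W = matrix(stats::rnorm(fan_in * units, 0, sqrt(2 / fan_in)),
                     fan_in, units),
          b = numeric(units))
        model$trainable[i] <- TRUE
      }
    }
  })
  model
}

#' Set the representation training mode
#'
#' Controls which layers back-propagation may update:
#' * `train_all` / `fine_tune` — every parameter trainable (`fine_tune`
#'   differs only in starting from an incoming trained state);
#' * `freeze_all_conv` — the whole convolutional representation frozen, only
#'   the decision layers train;
#' * `freeze_all_conv_but_last` — all convolutional layers frozen except the
#'   last one.
#'
#' @param model A `cnn_model`.
#' @param mode One of the four modes above.
#' @return The model with updated trainable flags.
#' @export
set_representation_mode <- function(model,
    mode = c("train_all", "fine_tune", "freeze_all_conv",
             "freeze_all_conv_but_last")) {
  mode <- match.arg(mode)
  arch <- model$architecture
  widx <- .weight_layer_indices(arch)
  conv_idx <- widx[widx <= arch$representation_end]
  model$trainable[widx] <- TRUE
  if (mode == "freeze_all_conv") {
    model$trainable[conv_idx] <- FALSE
  } else if (mode == "freeze_all_conv_but_last") {
    model$trainable[conv_idx] <- FALSE
    model$trainable[conv_idx[length(conv_idx)]] <- TRUE
  }
  model$mode <- mode
  model
}

#' Classification metrics from truth and predictions
#'
#' @param truth,pred Integer 1-based class indices.
#' @param n_classes Number of classes.
#' @param class_names Optional class names.
#' @return An object of class `classification_metrics`: global `accuracy`,
#'   per-class one-vs-rest `sensitivity` (TP / (TP + FN)) and `specificity`
#'   (TN / (TN + FP)), and the `confusion` matrix (rows = truth,
#'   columns = prediction).
#' @export
classification_metrics <- function(truth, pred, n_classes = max(truth, pred),
                                   class_names = NULL) {
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_classes))
  dimnames(cm) <- list(truth = class_names, prediction = class_names)
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  structure(list(accuracy = sum(tp) / total,
                 sensitivity = stats::setNames(tp / (tp + fn), class_names),
                 specificity = stats::setNames(tn / (tn + fp), class_names),
                 confusion = cm),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("<classification_metrics> accuracy %.4f\n", x$accuracy))
  df <- data.frame(sensitivity = round(x$sensitivity, 4),
                   specificity = round(x$specificity, 4))
  print(df)
  invisible(x)
}

#' Evaluate a model on a test subset
#'
#' @param model A `cnn_model`.
#' @param ds A scaled [spectra_dataset()].
#' @param test_indices Integer row indices of the held-out test subset.
#' @return A [classification_metrics()] object.
#' @export
evaluate <- function(model, ds, test_indices) {
  pred <- predict_classes(model, ds$matrix[test_indices, , drop = FALSE])
  classification_metrics(ds$labels[test_indices], pred,
                         n_classes = model$architecture$n_classes,
                         class_names = ds$class_names)
}

#' One stage of a learning protocol
#'
#' @param dataset A [spectra_dataset()].
#' @param mode Representation mode for this step (see
#'   [set_representation_mode()]); the first step of a protocol must be
#'   `train_all`.
#' @param cfg Optional [train_config()] override for this step.
#' @return An object of class `protocol_step`.
#' @export
protocol_step <- function(dataset,
    mode = c("train_all", "fine_tune", "freeze_all_conv",
             "freeze_all_conv_but_last"),
    cfg = NULL) {
  mode <- match.arg(mode)
  structure(list(dataset = dataset, mode = mode, cfg = cfg),
            class = "protocol_step")
}

# Execute a step sequence, threading representation parameters.
# init_model = NULL builds and He-initialises a fresh model at step 1
# (which must then be train_all). `iteration_seed` perturbs every step's
# initialisation/shuffling seed so repeated iterations are independent even
# when steps carry their own configs.
.run_steps <- function(steps, arch_name, cfg, init_model = NULL,
                       split_seed = cfg$seed, step_offset = 0L,
                       iteration_seed = 0L) {
  model <- init_model
  out_steps <- vector("list", length(steps))
  for (k in seq_along(steps)) {
    st <- steps[[k]]
    ds <- st$dataset
    if (!ds$scaled) ds <- scale_unit_interval(ds)
    kcfg <- st$cfg %||% cfg
    kcfg$seed <- kcfg$seed + as.integer(iteration_seed)
    gk <- k + step_offset
    # the split seed is keyed to the dataset (not the step position) so the
    # same dataset gets byte-identical splits in every protocol of a run
    ds_key <- length(ds$class_names) * 7L + nrow(ds$matrix) %% 97L
    split <- stratified_split(ds$labels, kcfg$ratios, seed = split_seed + ds_key)
    if (is.null(model)) {
      if (st$mode != "train_all")
        stop("the first step of a protocol must use mode 'train_all'")
      arch <- build_architecture(arch_name, ncol(ds$matrix),
                                 length(ds$class_names))
      model <- init_parameters(arch, seed = kcfg$seed + gk)
    } else {
      model <- replace_decision_head(model, length(ds$class_names),
                                     seed = kcfg$seed + 100L + gk)
      model <- set_representation_mode(model, st$mode)
    }
    fit <- train(model, ds, split, kcfg)
    model <- fit$model
    metrics <- evaluate(model, ds, split$test)
    out_steps[[k]] <- list(mode = st$mode, dataset = ds, split = split,
                           metrics = metrics, accuracy = metrics$accuracy,
                           model = model, history = fit$history)
  }
  structure(list(final_model = model, steps = out_steps,
                 arch_name = arch_name),
            class = "protocol_result")
}

#' Run a learning protocol
#'
#' Executes a sequence of [protocol_step()]s in order, carrying the learned
#' representation from one step to the next: the first step trains a freshly
#' initialised model, every later step replaces the decision head for its
#' task, applies its representation mode and trains. Each step is evaluated
#' on its own held-out stratified test subset.
#'
#' @param steps List of [protocol_step()]s (all datasets must share the bin
#'   count).
#' @param arch_name Architecture name (see [build_architecture()]).
#' @param cfg Default [train_config()] for steps without their own.
#' @param split_seed Seed base for the per-step stratified splits.
#' @return A `protocol_result`: `final_model` plus per-step mode, split,
#'   metrics, model snapshot and training history.
#' @export
run_protocol <- function(steps, arch_name = "variant_lecun",
                         cfg = train_config(), split_seed = cfg$seed) {
  nb <- vapply(steps, function(s) ncol(s$dataset$matrix), 0)
  if (length(unique(nb)) != 1)
    stop("all protocol datasets must share the same number of bins")
  .run_steps(steps, arch_name, cfg, init_model = NULL, split_seed = split_seed)
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s, %d steps\n", x$arch_name, length(x$steps)))
  for (k in seq_along(x$steps)) {
    s <- x$steps[[k]]
    cat(sprintf("  step %d [%-24s] %2d classes: accuracy %.4f\n", k, s$mode,
                length(s$dataset$class_names), s$accuracy))
  }
  invisible(x)
}

#' Named protocol presets over a task family
#'
#' Builds the step sequences of the four canonical protocols on a family from
#' [generate_task_family()] / [default_task_family()] (targets ordered
#' 12-class, 5-class, 2-class; the 2-class medium task plays the intermediate
#' role):
#' * `SCRATCH` — train the target task alone from scratch;
#' * `TRANSFER` — train on the source, freeze all conv layers, retrain the
#'   decision layers on the target;
#' * `SCENARIO_A` — source, fine-tune on the intermediate task, freeze all
#'   conv for the target;
#' * `SCENARIO_B` — source, fine-tune intermediate, fine-tune the 5-class
#'   task, then freeze all conv layers barring the last one for the target.
#'
#' @param name Protocol name.
#' @param family A task family list (`source`, `targets`).
#' @param target Which target dataset is the final task (default the 12-class,
#'   `family$targets[[1]]`).
#' @param source_cfg,intermediate_cfg,target_cfg Optional per-role
#'   [train_config()]s.
#' @param intermediate2_cfg Config of Scenario B's second fine-tune step
#'   (defaults to a gentler pass than `intermediate_cfg`: late cumulative
#'   steps use lower learning rates so earlier accumulated knowledge is
#'   preserved).
#' @return List of [protocol_step()]s for [run_protocol()].
#' @export
protocol_preset <- function(name = c("SCRATCH", "TRANSFER", "SCENARIO_A",
                                     "SCENARIO_B"),
                            family, target = family$targets[[1]],
                            source_cfg = NULL, intermediate_cfg = NULL,
                            target_cfg = NULL,
                            intermediate2_cfg = NULL) {
  name <- match.arg(name)
  if (is.null(intermediate2_cfg)) {
    intermediate2_cfg <- intermediate_cfg %||% train_config()
    intermediate2_cfg$lr <- intermediate2_cfg$lr / 10
    intermediate2_cfg$max_epochs <- min(intermediate2_cfg$max_epochs, 6L)
  }
  src <- function() protocol_step(family$source, "train_all", source_cfg)
  switch(name,
    SCRATCH = list(protocol_step(target, "train_all", target_cfg)),
    TRANSFER = list(src(),
                    protocol_step(target, "freeze_all_conv", target_cfg)),
    SCENARIO_A = list(src(),
                      protocol_step(family$targets[[3]], "fine_tune", intermediate_cfg),
                      protocol_step(target, "freeze_all_conv", target_cfg)),
    SCENARIO_B = list(src(),
                      protocol_step(family$targets[[3]], "fine_tune", intermediate_cfg),
                      protocol_step(family$targets[[2]], "fine_tune", intermediate2_cfg),
                      protocol_step(target, "freeze_all_conv_but_last", target_cfg)))
}

#' Retention of earlier tasks by a cumulative representation
#'
#' After a multi-step protocol, re-attaches each earlier step's saved decision
#' head onto the *final* representation and re-evaluates that step's test
#' subset, measuring how much accuracy the representation lost on earlier
#' tasks while accumulating later ones.
#'
#' @param result A `protocol_result` from [run_protocol()].
#' @return Data frame with one row per earlier step: accuracy at the time of
#'   the step, accuracy of the final representation with the step's head, and
#'   the loss (positive = degradation).
#' @export
evaluate_retention <- function(result) {
  n <- length(result$steps)
  final <- result$final_model
  rep_end <- final$architecture$representation_end
  rows <- list()
  for (k in seq_len(n - 1L)) {
    st <- result$steps[[k]]
    m <- st$model   # step-k architecture and decision parameters
    for (i in seq_along(m$architecture$layers)) {
      if (i <= rep_end && !is.null(final$params[[i]]))
        m$params[[i]] <- final$params[[i]]
    }
    acc <- evaluate(m, st$dataset, st$split$test)$accuracy
    rows[[k]] <- data.frame(step = k, mode = st$mode,
                            n_classes = length(st$dataset$class_names),
                            accuracy_then = st$accuracy,
                            accuracy_final_representation = acc,
                            loss = st$accuracy - acc)
  }
  do.call(rbind, rows)
}

#' Repeated-iteration experiment over one protocol
#'
#' Runs a named protocol `n_iterations` times. The task family is fixed; each
#' iteration draws fresh stratified 60/20/20 splits (seed `base_seed +
#' iteration`) and re-trains the whole protocol, mirroring repeated
#' cross-validation. Reports the final-step accuracy as mean +/- sd over
#' iterations, per architecture.
#'
#' @param protocol Protocol name (see [protocol_preset()]).
#' @param arch_names Character vector of architecture names.
#' @param family Task family from [generate_task_family()].
#' @param n_iterations Number of independent iterations (>= 2; default 10).
#' @param base_seed Base seed.
#' @param cfg Default [train_config()].
#' @param ... Passed to [protocol_preset()] (per-role configs, target choice).
#' @return An object of class `result_table`: data frame of per-cell mean/sd
#'   plus the per-iteration accuracy matrix in attribute `"iterations"`.
#' @export
run_experiment <- function(protocol, arch_names = "variant_lecun", family,
                           n_iterations = 10L, base_seed = 1L,
                           cfg = train_config(), ...) {
  if (n_iterations < 2) stop("n_iterations must be >= 2")
  acc <- matrix(NA_real_, n_iterations, length(arch_names),
                dimnames = list(NULL, arch_names))
  for (a in seq_along(arch_names)) {
    for (it in seq_len(n_iterations)) {
      icfg <- cfg
      icfg$seed <- as.integer(base_seed + it)
      steps <- protocol_preset(protocol, family, ...)
      res <- .run_steps(steps, arch_names[a], icfg,
                        split_seed = base_seed + it * 1000L,
                        iteration_seed = it * 131L)
      acc[it, a] <- res$steps[[length(res$steps)]]$accuracy
    }
  }
  tab <- data.frame(protocol = protocol, architecture = arch_names,
                    mean_accuracy = colMeans(acc),
                    sd_accuracy = apply(acc, 2, stats::sd))
  tab$formatted <- sprintf("%.2f +/- %.2f", tab$mean_accuracy, tab$sd_accuracy)
  attr(tab, "iterations") <- acc
  class(tab) <- c("result_table", "data.frame")
  tab
}

#' Paired comparison of learning protocols on one family
#'
#' Runs several protocols over the same iterations with byte-identical
#' per-iteration splits, sharing one source model per iteration across the
#' protocols that start from it (the source step is identical between them,
#' so training it once per iteration changes nothing but the run time).
#'
#' @param family Task family from [generate_task_family()].
#' @param protocols Character vector of protocol names.
#' @param arch_name Architecture name.
#' @param n_iterations Number of iterations (default 10).
#' @param base_seed Base seed.
#' @param cfg Default [train_config()].
#' @param source_cfg,intermediate_cfg,target_cfg Per-role config overrides.
#' @param reuse_source `"protocol"` trains the shared source step once per
#'   protocol; `"iteration"` (default) once per iteration; `"all"` once for
#'   the whole experiment. The source step is identical wherever it appears,
#'   so sharing it changes nothing but the run time.
#' @return List with `accuracy` (iterations x protocols matrix), `summary`
#'   (mean/sd data frame) and `results` (last iteration's protocol results).
#' @export
compare_protocols <- function(family,
                              protocols = c("SCRATCH", "TRANSFER", "SCENARIO_A"),
                              arch_name = "variant_lecun", n_iterations = 10L,
                              base_seed = 1L, cfg = train_config(),
                              source_cfg = NULL, intermediate_cfg = NULL,
                              target_cfg = NULL,
                              reuse_source = c("iteration", "all", "protocol")) {
  if (is.logical(reuse_source))
    reuse_source <- if (reuse_source) "iteration" else "protocol"
  reuse_source <- match.arg(reuse_source)
  acc <- matrix(NA_real_, n_iterations, length(protocols),
                dimnames = list(NULL, protocols))
  last <- list()
  shared_source <- NULL
  for (it in seq_len(n_iterations)) {
    icfg <- cfg
    icfg$seed <- as.integer(base_seed + it)
    split_seed <- as.integer(base_seed + it * 1000L)
    source_model <- if (reuse_source == "all") shared_source else NULL
    for (p in seq_along(protocols)) {
      steps <- protocol_preset(protocols[p], family,
                               source_cfg = source_cfg,
                               intermediate_cfg = intermediate_cfg,
                               target_cfg = target_cfg)
      first_is_source <- protocols[p] != "SCRATCH"
      if (first_is_source && reuse_source != "protocol" &&
          !is.null(source_model)) {
        res <- .run_steps(steps[-1], arch_name, icfg,
                          init_model = source_model, split_seed = split_seed,
                          step_offset = 1L, iteration_seed = it * 131L)
      } else {
        res <- .run_steps(steps, arch_name, icfg, split_seed = split_seed,
                          iteration_seed = it * 131L)
        if (first_is_source && reuse_source != "protocol") {
          source_model <- res$steps[[1]]$model
          if (reuse_source == "all" && is.null(shared_source))
            shared_source <- source_model
        }
      }
      acc[it, p] <- res$steps[[length(res$steps)]]$accuracy
      if (it == n_iterations) last[[protocols[p]]] <- res
    }
  }
  summary <- data.frame(protocol = protocols, mean_accuracy = colMeans(acc),
                        sd_accuracy = apply(acc, 2, stats::sd))
  list(accuracy = acc, summary = summary, results = last)
}

#' Welch t-test between two accuracy sequences
#'
#' Two-sided unequal-variance t-test on per-iteration accuracies. If both
#' sequences are constant the p-value is defined as 1 when they are equal and
#' 0 otherwise (documented convention; the test statistic is undefined there).
#'
#' @param runs_a,runs_b Numeric vectors of length >= 2.
#' @return p-value in \[0, 1\].
#' @export
compare_ttest <- function(runs_a, runs_b) {
  if (length(runs_a) < 2 || length(runs_b) < 2)
    stop("both sequences must have length >= 2")
  if (stats::sd(runs_a) == 0 && stats::sd(runs_b) == 0)
    return(if (isTRUE(all.equal(mean(runs_a), mean(runs_b)))) 1.0 else 0.0)
  stats::t.test(runs_a, runs_b, var.equal = FALSE)$p.value
}
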