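# Internal 1D-CNN engine: forward/backward passes over the layer list of a
# cnn_architecture, weighted cross-entropy losses, and an Adam optimiser.
# Signals travel as arrays dim (length, channels, batch) through the
# representation portion and as (batch, features) matrices after flatten;
# the batched conv/pool kernels live in src/conv1d.cpp.

# Rows of `mat` (batch x bins) as a (bins, 1, batch) array.
.as_input_cube <- function(mat) {
  array(t(mat), dim = c(ncol(mat), 1L, nrow(mat)))
}

# Forward through layers from..to. `state` is a cube or a matrix depending on
# where `from` sits. Returns list(state=..., caches=list) — caches are kept
# only when `train = TRUE` (dropout active, intermediates retained).
.forward_range <- function(model, state, from, to, train = FALSE) {
  layers <- model$architecture$layers
  caches <- if (train) vector("list", length(layers)) else NULL
  for (i in from:to) {
    l <- layers[[i]]
    if (l$kind == "conv") {
      p <- model$params[[i]]
      if (train) caches[[i]] <- list(X = state)
      state <- .conv1d_forward(state, p$W, p$b, l$kernel)
    } else if (l$kind == "act") {
      if (train) caches[[i]] <- list(X = state)
      if (is.matrix(state)) {
        neg <- state < 0
        state[neg] <- state[neg] * l$slope
      } else {
        state <- .leaky_relu_forward(state, l$slope)
      }
    } else if (l$kind == "pool") {
      r <- .maxpool_forward(state, l$size)
      if (train) caches[[i]] <- list(argmax = r$argmax, L = dim(state)[1])
      state <- r$Y
    } else if (l$kind == "flatten") {
      d <- dim(state)
      if (train) caches[[i]] <- list(len = d[1], ch = d[2])
      state <- t(matrix(state, d[1] * d[2], d[3]))
    } else if (l$kind == "dense" || l$kind == "output") {
      p <- model$params[[i]]
      if (train) caches[[i]] <- list(A = state)
      state <- sweep(state %*% p$W, 2, p$b, "+")
    } else if (l$kind == "dropout") {
      if (train) {
        mask <- matrix(stats::runif(length(state)) >= l$rate,
                       nrow(state), ncol(state)) / (1 - l$rate)
        caches[[i]] <- list(mask = mask)
        state <- state * mask
      }
      # inference: identity (inverted dropout)
    }
  }
  list(state = state, caches = caches)
}

.head_probabilities <- function(logits, activation) {
  if (activation == "softmax") {
    z <- logits - apply(logits, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    1 / (1 + exp(-logits))
  }
}

# Weighted cross-entropy loss and gradient w.r.t. logits.
# labels are 1-based class indices; weights is the per-class weight vector.
.loss_and_grad <- function(logits, labels, weights, activation) {
  B <- nrow(logits)
  w <- weights[labels]
  if (activation == "softmax") {
    P <- .head_probabilities(logits, "softmax")
    idx <- cbind(seq_len(B), labels)
    loss <- -mean(w * log(pmax(P[idx], 1e-12)))
    G <- P
    G[idx] <- G[idx] - 1
    G <- G * (w / B)
  } else {
    y <- as.numeric(labels == 2L)   # class 2 is the "positive" class
    p <- .head_probabilities(logits, "sigmoid")[, 1]
    loss <- -mean(w * (y * log(pmax(p, 1e-12)) +
                       (1 - y) * log(pmax(1 - p, 1e-12))))
    G <- matrix((p - y) * w / B, ncol = 1)
  }
  list(loss = loss, grad = G)
}

# Backward from the output gradient down to (and including) layer `from`.
# Returns list of gradients for weight layers: grads[[i]] = list(W=, b=).
.backward_range <- function(model, caches, dstate, from, to) {
  layers <- model$architecture$layers
  grads <- vector("list", length(layers))
  stop_at <- from
  for (i in to:from) {
    l <- layers[[i]]
    need_dx <- i > stop_at
    if (l$kind == "output" || l$kind == "dense") {
      A <- caches[[i]]$A
      grads[[i]] <- list(W = crossprod(A, dstate), b = colSums(dstate))
      if (need_dx) dstate <- tcrossprod(dstate, model$params[[i]]$W)
    } else if (l$kind == "dropout") {
      dstate <- dstate * caches[[i]]$mask
    } else if (l$kind == "flatten") {
      cc <- caches[[i]]
      dstate <- array(t(dstate), dim = c(cc$len, cc$ch, nrow(dstate)))
    } else if (l$kind == "act") {
      X <- caches[[i]]$X
      if (is.matrix(X)) {
        slope_mask <- X >= 0
        dstate <- dstate * (slope_mask + (!slope_mask) * l$slope)
      } else {
        dstate <- .leaky_relu_backward(X, dstate, l$slope)
      }
    } else if (l$kind == "pool") {
      dstate <- .maxpool_backward(caches[[i]]$argmax, dstate, caches[[i]]$L)
    } else if (l$kind == "conv") {
      r <- .conv1d_backward(caches[[i]]$X, model$params[[i]]$W, dstate,
                            l$kernel, need_dx)
      grads[[i]] <- list(W = r$dW, b = r$db)
      if (need_dx) dstate <- r$dX
    }
  }
  grads
}

.adam_init <- function(model, layer_idx) {
  st <- list(t = 0L, m = list())
  for (i in layer_idx) {
    p <- model$params[[i]]
    st$m[[as.character(i)]] <- list(mW = p$W * 0, vW = p$W * 0,
                                    mb = p$b * 0, vb = p$b * 0)
  }
  st
}

.adam_step <- function(model, grads, state, layer_idx, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in layer_idx) {
    g <- grads[[i]]
    if (is.null(g)) next
    key <- as.character(i)
    s <- state$m[[key]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    model$params[[i]]$W <- model$params[[i]]$W -
      lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    model$params[[i]]$b <- model$params[[i]]$b -
      lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state$m[[key]] <- s
  }
  list(model = model, state = state)
}

#' Class-probability predictions of a CNN model
#'
#' @param model A [init_parameters()] / [train()] model state.
#' @param mat Matrix of spectra (rows) with `input_length` bins, scaled to
#'   \[0, 1\].
#' @param batch_size Forward-pass batch size.
#' @return An `n x n_classes` matrix of class probabilities (for a sigmoid
#'   head, column 1 is the negative and column 2 the positive class).
#' @export
predict_proba <- function(model, mat, batch_size = 64L) {
  arch <- model$architecture
  if (ncol(mat) != arch$input_length)
    stop(sprintf("spectra have %d bins but model expects %d",
                 ncol(mat), arch$input_length))
  n <- nrow(mat)
  out <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    X <- .as_input_cube(mat[idx, , drop = FALSE])
    logits <- .forward_range(model, X, 1L, length(arch$layers))$state
    P <- .head_probabilities(logits, arch$head_activation)
    if (arch$head_activation == "sigmoid")
      P <- cbind(1 - P[, 1], P[, 1])
    out <- rbind(out, P)
  }
  colnames(out) <- NULL
  out
}

#' Class predictions of a CNN model
#' @inheritParams predict_proba
#' @return Integer vector of 1-based class indices (argmax; 0.5 threshold for
#'   a sigmoid head).
#' @export
predict_classes <- function(model, mat, batch_size = 64L) {
  max.col(predict_proba(model, mat, batch_size), ties.method = "first")
}
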