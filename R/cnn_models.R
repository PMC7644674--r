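#' 1D-CNN architecture specification
#'
#' Builds one of the three reference 1D convolutional architectures used for
#' binned-spectrum classification, as an ordered list of layer
#' specifications split into a *representation* portion (convolution and
#' pooling) and a *decision* portion (flatten, fully connected and output):
#'
#' * `variant_lecun` — 4 weight-bearing layers:
#'   conv(16, k=21), pool(4), conv(32, k=11), pool(4), dense(128), output.
#' * `variant_lenet` — 5 weight-bearing layers: as above plus conv(64, k=11),
#'   pool(4) and a dense(256) head.
#' * `variant_vgg9` — 9 weight-bearing layers: three blocks of two
#'   conv(32/64/128, k=9) followed by pool(4), then dense(512), dense(256),
#'   output.
#'
#' All convolutions are "valid" (no zero padding — binned spectra start and
#' end at zero so nothing is lost at the borders) with Leaky ReLU (slope
#' 0.01) activations; dense layers carry dropout 0.5. The output head is a
#' single sigmoid unit for binary problems and a softmax over `n_classes`
#' otherwise. Filter counts and kernel lengths are package defaults
#' (overridable through `filters`, `kernels`, `dense_units`); kernels are
#' longer than typical image kernels because spectral peak features span tens
#' of bins.
#'
#' @param name One of `"variant_lecun"`, `"variant_lenet"`, `"variant_vgg9"`.
#' @param input_length Number of bins of the input spectra (>= 64).
#' @param n_classes Number of classes (>= 2).
#' @param filters,kernels,dense_units Optional overrides of the per-variant
#'   defaults (integer vectors; lengths must match the variant's conv and
#'   dense layer counts).
#' @param dropout Dropout rate on dense layers.
#' @return An object of class `cnn_architecture` with fields `name`, `layers`,
#'   `representation_end` (index of the last conv/pool layer), `input_length`,
#'   `n_classes`, `head_activation` and `shapes` (per-layer output shapes).
#' @export
build_architecture <- function(name = c("variant_lecun", "variant_lenet", "variant_vgg9"),
                               input_length, n_classes,
                               filters = NULL, kernels = NULL,
                               dense_units = NULL, dropout = 0.5) {
  name <- match.arg(name)
  if (input_length < 64) stop("input_length must be >= 64")
  if (n_classes < 2) stop("n_classes must be >= 2")
  defs <- switch(name,
    variant_lecun = list(filters = c(16L, 32L), kernels = c(21L, 11L),
                         pool_after = c(1L, 2L), dense = 128L),
    variant_lenet = list(filters = c(16L, 32L, 64L), kernels = c(21L, 11L, 11L),
                         pool_after = c(1L, 2L, 3L), dense = 256L),
    variant_vgg9  = list(filters = c(32L, 32L, 64L, 64L, 128L, 128L),
                         kernels = rep(9L, 6L), pool_after = c(2L, 4L, 6L),
                         dense = c(512L, 256L)))
  if (!is.null(filters)) defs$filters <- as.integer(filters)
  if (!is.null(kernels)) defs$kernels <- as.integer(kernels)
  if (!is.null(dense_units)) defs$dense <- as.integer(dense_units)
  stopifnot(length(defs$filters) == length(defs$kernels))

  layers <- list()
  len <- as.integer(input_length); ch <- 1L
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  for (i in seq_along(defs$filters)) {
    k <- defs$kernels[i]
    if (len - k + 1L < 1L)
      stop(sprintf("input too short: conv layer %d needs length >= %d, has %d",
                   i, k, len))
    add(list(kind = "conv", filters = defs$filters[i], kernel = k,
             in_channels = ch, in_length = len))
    len <- len - k + 1L; ch <- defs$filters[i]
    add(list(kind = "act", slope = 0.01))
    if (i %in% defs$pool_after) {
      if (len < 4L)
        stop(sprintf("input too short: pool after conv %d gets length %d", i, len))
      add(list(kind = "pool", size = 4L, in_length = len))
      len <- len %/% 4L
    }
  }
  representation_end <- length(layers)
  add(list(kind = "flatten", in_length = len, in_channels = ch))
  feat <- len * ch
  for (u in defs$dense) {
    add(list(kind = "dense", units = as.integer(u), in_features = feat))
    add(list(kind = "act", slope = 0.01))
    if (dropout > 0) add(list(kind = "dropout", rate = dropout))
    feat <- as.integer(u)
  }
  head_activation <- if (n_classes == 2L) "sigmoid" else "softmax"
  out_units <- if (head_activation == "sigmoid") 1L else as.integer(n_classes)
  add(list(kind = "output", units = out_units, in_features = feat,
           activation = head_activation))

  structure(list(name = name, layers = layers,
                 representation_end = representation_end,
                 input_length = as.integer(input_length),
                 n_classes = as.integer(n_classes),
                 head_activation = head_activation,
                 dropout = dropout),
            class = "cnn_architecture")
}

#' @export
print.cnn_architecture <- function(x, ...) {
  cat(sprintf("<cnn_architecture> %s: input %d bins, %d classes (%s head)\n",
              x$name, x$input_length, x$n_classes, x$head_activation))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    desc <- switch(l$kind,
      conv = sprintf("conv1d %d filters, kernel %d (valid)", l$filters, l$kernel),
      act = sprintf("leaky relu (%.2g)", l$slope),
      pool = "max pool 4",
      flatten = sprintf("flatten -> %d features", l$in_length * l$in_channels),
      dense = sprintf("dense %d", l$units),
      dropout = sprintf("dropout %.2g", l$rate),
      output = sprintf("output %d (%s)", l$units, l$activation))
    marker <- if (i == x$representation_end) "  <- representation ends" else ""
    cat(sprintf("  %2d. %s%s\n", i, desc, marker))
  }
  cat(sprintf("  weight-bearing layers: %d, parameters: %s\n",
              n_weight_layers(x), format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# indices of layers that carry parameters
.weight_layer_indices <- function(arch) {
  which(vapply(arch$layers, function(l) l$kind %in% c("conv", "dense", "output"),
               logical(1)))
}

#' Number of weight-bearing layers of an architecture
#' @param arch A [build_architecture()] result.
#' @export
n_weight_layers <- function(arch) length(.weight_layer_indices(arch))

#' Total trainable parameter count of an architecture
#' @param arch A [build_architecture()] result.
#' @export
count_parameters <- function(arch) {
  total <- 0
  for (l in arch$layers) {
    if (l$kind == "conv") total <- total + l$kernel * l$in_channels * l$filters + l$filters
    if (l$kind %in% c("dense", "output")) total <- total + l$in_features * l$units + l$units
  }
  total
}

#' Initialise model parameters (He normal)
#'
#' Conv and dense weights are drawn from `Normal(0, 2 / fan_in)` (He
#' initialisation, matched to rectifier activations); all biases start at
#' zero. The output layer is initialised the same way with its own fan-in.
#' Reproducible for a fixed seed.
#'
#' @param arch A [build_architecture()] result.
#' @param seed Integer seed.
#' @return An object of class `cnn_model` ("model state"): the architecture,
#'   a per-layer list of parameter tensors, per-layer trainable flags and the
#'   init seed.
#' @export
init_parameters <- function(arch, seed = 1L) {
  params <- vector("list", length(arch$layers))
  with_seed(seed, {
    for (i in seq_along(arch$layers)) {
      l <- arch$layers[[i]]
      if (l$kind == "conv") {
        fan_in <- l$kernel * l$in_channels
        params[[i]] <- list(
          W = matrix(stats::rnorm(fan_in * l$filters, 0, sqrt(2 / fan_in)),
                     fan_in, l$filters),
          b = numeric(l$filters))
      } else if (l$kind %in% c("dense", "output")) {
        fan_in <- l$in_features
        params[[i]] <- list(
          W = matrix(stats::rnorm(fan_in * l$units, 0, sqrt(2 / fan_in)),
                     fan_in, l$units),
          b = numeric(l$units))
      }
    }
  })
  trainable <- vapply(arch$layers, function(l)
    l$kind %in% c("conv", "dense", "output"), logical(1))
  structure(list(architecture = arch, params = params, trainable = trainable,
                 init_seed = as.integer(seed)),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  arch <- x$architecture
  cat(sprintf("<cnn_model> %s (%d bins -> %d classes), seed %d\n",
              arch$name, arch$input_length, arch$n_classes, x$init_seed))
  wi <- .weight_layer_indices(arch)
  frozen <- sum(!x$trainable[wi])
  cat(sprintf("  %d weight layers (%d frozen), %s parameters\n",
              length(wi), frozen, format(count_parameters(arch), big.mark = ",")))
  invisible(x)
}

#' Balanced inverse-frequency class weights
#'
#' Loss weights for under-represented classes:
#' `weight_c = n_total / (n_classes * n_c)`, so the sample-weighted mean of
#' the weights is 1 and a balanced dataset gets all-ones.
#'
#' @param labels Integer (1-based) or factor class labels.
#' @param n_classes Total number of classes (defaults to the largest label).
#' @return Named numeric vector of per-class weights.
#' @export
class_weights <- function(labels, n_classes = NULL) {
  if (is.factor(labels) || is.character(labels)) {
    f <- factor(labels)
    labels <- as.integer(f)
    nms <- levels(f)
  } else nms <- NULL
  if (is.null(n_classes)) n_classes <- max(labels)
  counts <- tabulate(labels, nbins = n_classes)
  if (any(counts == 0)) stop("every class must have at least one sample")
  w <- length(labels) / (n_classes * counts)
  names(w) <- nms %||% paste0("class", seq_len(n_classes))
  w
}
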