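#' Bin grid for fixed-width m/z bucketing
#'
#' Describes a regular grid of half-open bins `[edge_i, edge_{i+1})` covering
#' `[mass_min, mass_max)`. Binning profile spectra onto such a grid ("spectral
#' bucketing") is the standard way of turning variable-length (m/z, intensity)
#' traces into equal-length feature vectors prior to classification.
#'
#' @param mass_min,mass_max Mass range in Da; `mass_max > mass_min`.
#' @param bin_width Bin width in Da, positive. 0.1 Da is the common choice for
#'   Q-TOF profile data.
#' @return An object of class `bin_grid` with fields `mass_min`, `mass_max`,
#'   `bin_width` and `n_bins`.
#' @examples
#' bin_grid(100, 1600, 0.1)   # 15,000 bins
#' @export
bin_grid <- function(mass_min, mass_max, bin_width) {
  nb <- n_bins(mass_min, mass_max, bin_width)
  structure(list(mass_min = mass_min, mass_max = mass_max,
                 bin_width = bin_width, n_bins = nb),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> [%g, %g) Da, width %g Da, %d bins\n",
              x$mass_min, x$mass_max, x$bin_width, x$n_bins))
  invisible(x)
}

#' Number of bins of a fixed-width grid
#'
#' @inheritParams bin_grid
#' @return Integer bin count, `round((mass_max - mass_min) / bin_width)`.
#' @examples
#' n_bins(100, 1600, 0.1)  # 15000
#' n_bins(100, 2000, 0.1)  # 19000
#' @export
n_bins <- function(mass_min, mass_max, bin_width) {
  if (!is.numeric(mass_min) || !is.numeric(mass_max) || !is.numeric(bin_width))
    stop("mass_min, mass_max and bin_width must be numeric")
  if (mass_max <= mass_min)
    stop("invalid mass range: mass_max must exceed mass_min")
  if (bin_width <= 0)
    stop("bin_width must be positive")
  as.integer(round((mass_max - mass_min) / bin_width))
}

#' Bin centres of a grid
#' @param grid A [bin_grid()].
#' @return Numeric vector of the `n_bins` bin mid-points in Da.
#' @export
bin_centers <- function(grid) {
  grid$mass_min + (seq_len(grid$n_bins) - 0.5) * grid$bin_width
}

#' Raw profile spectrum
#'
#' One acquisition as ordered (m/z, intensity) pairs, kept exactly as imported
#' (no preprocessing). m/z must be strictly increasing and intensities
#' non-negative.
#'
#' @param mz Strictly increasing numeric vector of m/z values in Da.
#' @param intensity Non-negative numeric vector, same length as `mz`.
#' @param id Opaque spectrum identifier.
#' @return An object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(mz, intensity, id = "spectrum") {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("mz values must be strictly increasing")
  if (any(intensity < 0))
    stop("intensities must be non-negative")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 id = id),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("<raw_spectrum> '%s': %d points, m/z %.4g-%.4g\n",
              x$id, length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

# 1-based bin index of each m/z on a grid; NA for out-of-range points.
# A small relative tolerance snaps values sitting a few ulp below a bin edge
# up onto it, so that e.g. m/z == 100.1 on a 0.1 Da grid starting at 100
# lands in bin 2 despite (100.1 - 100)/0.1 < 1 in floating point.
.bin_index <- function(mz, grid) {
  r <- (mz - grid$mass_min) / grid$bin_width
  i <- floor(r + 1e-9) + 1
  i[i < 1 | i > grid$n_bins] <- NA_integer_
  as.integer(i)
}

#' Project a raw spectrum onto a bin grid
#'
#' Each point whose m/z lies in `[mass_min, mass_max)` contributes to exactly
#' one half-open bin; points outside the range are dropped (their count is
#' attached as attribute `n_dropped`). The default aggregate `sum` conserves
#' total in-range ion count; `mean` and `max` are also available.
#'
#' @param raw A [raw_spectrum()].
#' @param grid A [bin_grid()].
#' @param aggregate How multiple points in one bin are combined.
#' @return Numeric vector of length `grid$n_bins`.
#' @export
bin_spectrum <- function(raw, grid, aggregate = c("sum", "mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (!inherits(raw, "raw_spectrum"))
    raw <- raw_spectrum(raw$mz, raw$intensity, raw$id %||% "spectrum")
  idx <- .bin_index(raw$mz, grid)
  keep <- !is.na(idx)
  n_dropped <- sum(!keep)
  out <- numeric(grid$n_bins)
  if (any(keep)) {
    ii <- idx[keep]; vv <- raw$intensity[keep]
    if (aggregate == "sum") {
      s <- rowsum(vv, ii)
      out[as.integer(rownames(s))] <- s[, 1L]
    } else if (aggregate == "mean") {
      s <- rowsum(vv, ii)
      cnt <- rowsum(rep(1, length(vv)), ii)
      out[as.integer(rownames(s))] <- s[, 1L] / cnt[, 1L]
    } else {
      m <- vapply(split(vv, ii), max, numeric(1))
      out[as.integer(names(m))] <- m
    }
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

# Bin many spectra sharing one dense m/z axis (columns of `mat`) in one pass.
# Used by the synthetic generator; sum aggregation.
.bin_matrix <- function(mat, dense_mz, grid) {
  idx <- .bin_index(dense_mz, grid)
  keep <- !is.na(idx)
  s <- rowsum(t(mat[, keep, drop = FALSE]), idx[keep])
  out <- matrix(0, nrow(mat), grid$n_bins)
  out[, as.integer(rownames(s))] <- t(s)
  out
}

#' Binned, labelled spectra dataset
#'
#' The container every model in this package consumes: an
#' `n_spectra x n_bins` non-negative intensity matrix plus class labels and
#' the generating [bin_grid()], so that feature index and m/z remain mutually
#' recoverable.
#'
#' @param matrix Numeric matrix, spectra in rows, bins in columns.
#' @param labels Integer vector (1-based class indices) or factor/character
#'   vector convertible to one.
#' @param class_names Character vector of class names; defaults to the label
#'   levels.
#' @param grid The [bin_grid()] the columns live on.
#' @param sample_ids Optional per-spectrum identifiers.
#' @param scaled Logical; `TRUE` once intensities have been mapped into
#'   \[0, 1\] by [scale_unit_interval()].
#' @return An object of class `spectra_dataset`.
#' @export
spectra_dataset <- function(matrix, labels, class_names = NULL, grid,
                            sample_ids = NULL, scaled = FALSE) {
  if (is.factor(labels) || is.character(labels)) {
    f <- factor(labels, levels = if (is.null(class_names)) unique(as.character(labels)) else class_names)
    class_names <- levels(f)
    labels <- as.integer(f)
  }
  labels <- as.integer(labels)
  if (is.null(class_names))
    class_names <- paste0("class", seq_len(max(labels)))
  if (nrow(matrix) != length(labels))
    stop("matrix row count must equal length(labels)")
  if (any(labels < 1L) || any(labels > length(class_names)))
    stop("labels out of range of class_names")
  if (ncol(matrix) != grid$n_bins)
    stop(sprintf("matrix has %d columns but grid has %d bins",
                 ncol(matrix), grid$n_bins))
  if (is.null(sample_ids))
    sample_ids <- paste0("s", seq_len(nrow(matrix)))
  structure(list(matrix = matrix, labels = labels, class_names = class_names,
                 grid = grid, sample_ids = sample_ids, scaled = isTRUE(scaled)),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("<spectra_dataset> %d spectra x %d bins, %d classes%s\n",
              nrow(x$matrix), ncol(x$matrix), length(x$class_names),
              if (x$scaled) " (scaled)" else ""))
  tab <- table(factor(x$class_names[x$labels], levels = x$class_names))
  for (nm in names(tab)) cat(sprintf("  %-30s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$matrix)

#' Scale each spectrum linearly into the unit interval
#'
#' Maps every row by `(x - min) / (max - min)` using that row's own minimum
#' and maximum (per-spectrum scaling removes the global intensity nuisance
#' between heterogeneous acquisitions). A constant row maps to all zeros.
#' With `per = "dataset"` a single global min/max is used instead.
#'
#' @param ds A [spectra_dataset()].
#' @param per `"spectrum"` (default) or `"dataset"`.
#' @return The dataset with values in \[0, 1\] and `scaled = TRUE`.
#' @export
scale_unit_interval <- function(ds, per = c("spectrum", "dataset")) {
  per <- match.arg(per)
  m <- ds$matrix
  if (per == "spectrum") {
    lo <- apply(m, 1, min)
    hi <- apply(m, 1, max)
    rng <- hi - lo
    rng[rng == 0] <- 1  # constant rows -> zeros
    m <- (m - lo) / rng
  } else {
    lo <- min(m); hi <- max(m)
    if (hi > lo) m <- (m - lo) / (hi - lo) else m[] <- 0
  }
  ds$matrix <- m
  ds$scaled <- TRUE
  ds
}

#' Stratified train/validation/test split
#'
#' Splits sample indices into disjoint, exhaustive train/validation/test sets
#' whose per-class counts stay within one sample of `n_c * ratio` (largest
#' remainder apportionment after a seeded per-class shuffle), preserving the
#' original proportion of minority classes.
#'
#' @param labels Integer or factor class labels.
#' @param ratios Length-3 positive vector summing to 1; default 60/20/20.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return An object of class `split_indices`: list of integer vectors
#'   `train`, `validation`, `test` plus the `seed`.
#' @export
stratified_split <- function(labels, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ratios) != 3 || any(ratios <= 0))
    stop("ratios must be three positive numbers")
  if (abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must sum to 1")
  labels <- as.integer(if (is.factor(labels)) labels else factor(labels, levels = unique(labels)))
  small <- table(labels)
  if (any(small < 3))
    warning("classes with fewer than 3 samples cannot be represented in every subset; best-effort assignment")
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      exact <- n * ratios
      base <- floor(exact)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      cuts <- cumsum(base)
      out$train <- c(out$train, idx[seq_len(base[1])])
      if (base[2] > 0)
        out$validation <- c(out$validation, idx[(cuts[1] + 1):cuts[2]])
      if (base[3] > 0)
        out$test <- c(out$test, idx[(cuts[2] + 1):cuts[3]])
    }
  })
  structure(list(train = sort(out$train), validation = sort(out$validation),
                 test = sort(out$test), seed = as.integer(seed)),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> train %d / validation %d / test %d (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}

#' Similarity between two binned spectra
#'
#' Pearson or cosine correlation between equal-length intensity vectors, the
#' two standard spectrum-similarity QC metrics.
#'
#' @param a,b Numeric vectors of equal length (>= 2).
#' @param method `"pearson"` or `"cosine"`.
#' @return A coefficient in \[-1, 1\].
#' @export
spectrum_similarity <- function(a, b, method = c("pearson", "cosine")) {
  method <- match.arg(method)
  if (length(a) != length(b) || length(a) < 2)
    stop("a and b must have equal length >= 2")
  if (method == "pearson") {
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("pearson similarity undefined for constant input")
    stats::cor(a, b)
  } else {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0)
      stop("cosine similarity undefined for zero vector")
    sum(a * b) / (na * nb)
  }
}

#' Read a spectra dataset from delimited text
#'
#' Two CSV dialects are supported (UTF-8, comma-delimited, '.' decimal):
#' * `wide_csv`: one row per spectrum; columns `sample_id`, `label`, then one
#'   column per bin (named `mz_<centre>`). Returns a [spectra_dataset()]
#'   (the grid is rebuilt from the bin-centre column names).
#' * `long_csv`: columns `spectrum_id`, `label`, `mz`, `intensity`, one row
#'   per profile point; m/z must be sorted increasing within each spectrum.
#'   Returns a list of [raw_spectrum()] objects with a `labels` attribute.
#'
#' @param path File path.
#' @param format `"wide_csv"` or `"long_csv"`.
#' @return See Details.
#' @export
read_dataset <- function(path, format = c("wide_csv", "long_csv")) {
  format <- match.arg(format)
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = TRUE)
  if (format == "wide_csv") {
    need <- c("sample_id", "label")
    if (!all(need %in% names(dt)))
      stop("wide_csv requires 'sample_id' and 'label' columns")
    if (anyNA(dt))
      stop(sprintf("missing values (ragged rows?) at row %d",
                   which(rowSums(is.na(dt)) > 0)[1]))
    bincols <- grep("^mz_", names(dt), value = TRUE)
    if (length(bincols) < 2) stop("wide_csv needs at least two mz_* columns")
    centers <- as.numeric(sub("^mz_", "", bincols))
    m <- as.matrix(dt[, bincols, with = FALSE])
    neg <- which(rowSums(m < 0) > 0)
    if (length(neg))
      stop(sprintf("negative intensity at row %d", neg[1]))
    w <- centers[2] - centers[1]
    grid <- bin_grid(centers[1] - w / 2, centers[length(centers)] + w / 2, w)
    spectra_dataset(unname(m), labels = as.character(dt$label), grid = grid,
                    sample_ids = as.character(dt$sample_id))
  } else {
    need <- c("spectrum_id", "label", "mz", "intensity")
    if (!all(need %in% names(dt)))
      stop("long_csv requires columns spectrum_id, label, mz, intensity")
    ids <- unique(dt$spectrum_id)
    labels <- character(length(ids))
    spectra <- vector("list", length(ids))
    for (k in seq_along(ids)) {
      rows <- dt[dt$spectrum_id == ids[k], ]
      if (any(diff(rows$mz) <= 0))
        stop(sprintf("unsorted m/z in spectrum '%s'", ids[k]))
      if (any(rows$intensity < 0))
        stop(sprintf("negative intensity in spectrum '%s'", ids[k]))
      spectra[[k]] <- raw_spectrum(rows$mz, rows$intensity, id = as.character(ids[k]))
      labels[k] <- as.character(rows$label[1])
    }
    attr(spectra, "labels") <- labels
    spectra
  }
}

#' Write a spectra dataset to delimited text
#'
#' Inverse of [read_dataset()]; `write_dataset` then `read_dataset` round-trips
#' losslessly up to float formatting.
#'
#' @param x A [spectra_dataset()] (wide) or list of [raw_spectrum()] with a
#'   `labels` attribute (long).
#' @param path Output file path.
#' @param format `"wide_csv"` or `"long_csv"`.
#' @export
write_dataset <- function(x, path, format = c("wide_csv", "long_csv")) {
  format <- match.arg(format)
  if (format == "wide_csv") {
    stopifnot(inherits(x, "spectra_dataset"))
    centers <- bin_centers(x$grid)
    m <- x$matrix
    colnames(m) <- paste0("mz_", format(centers, trim = TRUE, digits = 15))
    dt <- data.table::data.table(sample_id = x$sample_ids,
                                 label = x$class_names[x$labels])
    dt <- cbind(dt, data.table::as.data.table(m))
    data.table::fwrite(dt, path)
  } else {
    labels <- attr(x, "labels")
    if (is.null(labels)) labels <- rep("unknown", length(x))
    parts <- lapply(seq_along(x), function(k) {
      data.table::data.table(spectrum_id = x[[k]]$id, label = labels[k],
                             mz = x[[k]]$mz, intensity = x[[k]]$intensity)
    })
    data.table::fwrite(data.table::rbindlist(parts), path)
  }
  invisible(path)
}

#' Subset a spectra dataset by row index
#' @param ds A [spectra_dataset()].
#' @param idx Integer row indices.
#' @return A [spectra_dataset()] with the selected spectra.
#' @export
subset_dataset <- function(ds, idx) {
  spectra_dataset(ds$matrix[idx, , drop = FALSE], ds$labels[idx],
                  ds$class_names, ds$grid, ds$sample_ids[idx], ds$scaled)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
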