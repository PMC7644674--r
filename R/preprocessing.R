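#' Configuration of the conventional preprocessing track
#'
#' Parameters of the five-step pipeline (log transform, SNIP baseline
#' subtraction, TIC normalisation, per-class cubic-warp alignment, MAD peak
#' detection) feeding the conventional ML baselines.
#'
#' @param snip_iterations SNIP clipping iterations (expanding half-window).
#' @param mad_k SNR threshold: a peak must exceed `mad_k` times the MAD-based
#'   noise estimate.
#' @param halfwindow Half-window in bins for peak-apex detection.
#' @param match_tolerance Maximum distance in Da when matching peaks to a
#'   reference peak list.
#' @param log_offset Offset of the log-intensity transform.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(snip_iterations = 40L, mad_k = 3, halfwindow = 20L,
                              match_tolerance = 0.5, log_offset = 1) {
  vals <- c(snip_iterations, mad_k, halfwindow, match_tolerance, log_offset)
  if (any(vals <= 0)) stop("all preprocessing parameters must be positive")
  structure(list(snip_iterations = as.integer(snip_iterations), mad_k = mad_k,
                 halfwindow = as.integer(halfwindow),
                 match_tolerance = match_tolerance, log_offset = log_offset),
            class = "preprocess_config")
}

#' Log-intensity transform
#'
#' Elementwise `log(offset + x) - log(offset)`, a strictly monotone map that
#' sends zero to zero and attenuates the large dynamic range of peak
#' intensities.
#'
#' @param x Non-negative spectrum vector.
#' @param offset Positive offset (default 1).
#' @return Transformed vector.
#' @export
log_transform <- function(x, offset = 1) {
  if (any(x < 0)) stop("log_transform requires non-negative intensities")
  log(offset + x) - log(offset)
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive non-linear iterative peak-clipping: the spectrum is
#' mapped through the LLS (log-log-square-root) compression, clipped for
#' `m = 1..iterations` by `y_i <- min(y_i, (y_{i-m} + y_{i+m}) / 2)`, and
#' mapped back. The result never exceeds the signal, so subtracting it leaves
#' a non-negative peak residual.
#'
#' @param x Non-negative spectrum vector.
#' @param iterations Number of clipping passes (must be < `length(x) / 2`).
#' @param lls Apply the LLS transform (default) or clip on the raw scale.
#' @return Baseline vector, elementwise `<= x`.
#' @export
snip_baseline <- function(x, iterations = 40L, lls = TRUE) {
  n <- length(x)
  if (any(x < 0)) stop("snip_baseline requires non-negative intensities")
  if (iterations < 1) stop("iterations must be >= 1")
  if (iterations >= n / 2)
    stop("iterations must be smaller than half the spectrum length")
  v <- if (lls) log(log(sqrt(x + 1) + 1) + 1) else x
  for (m in seq_len(iterations)) {
    mid <- (m + 1L):(n - m)
    avg <- (v[mid - m] + v[mid + m]) / 2
    v[mid] <- pmin(v[mid], avg)
  }
  b <- if (lls) (exp(exp(v) - 1) - 1)^2 - 1 else v
  pmin(b, x)  # guard float round-trip error of the LLS inverse
}

#' Total-ion-count normalisation
#'
#' Divides a spectrum by its summed intensity so the output sums to one;
#' proportions between bins are preserved and the result is invariant to
#' overall intensity scaling.
#'
#' @param x Spectrum vector with `sum(x) > 0`.
#' @return Normalised vector.
#' @export
tic_normalize <- function(x) {
  s <- sum(x)
  if (s <= 0) stop("TIC normalisation undefined for an all-zero spectrum")
  x / s
}

#' Peak list
#' @param apex_mz Apex positions (Da or bin index), increasing.
#' @param apex_intensity Apex intensities.
#' @param snr Per-peak signal-to-noise ratios.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(apex_mz, apex_intensity, snr = rep(Inf, length(apex_mz))) {
  o <- order(apex_mz)
  structure(list(apex_mz = apex_mz[o], apex_intensity = apex_intensity[o],
                 snr = snr[o]),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks\n", length(x$apex_mz)))
  invisible(x)
}

#' @export
length.peak_list <- function(x) length(x$apex_mz)

#' MAD-thresholded peak detection
#'
#' The noise scale is estimated robustly as
#' `1.4826 * median(|x - median(x)|)`; a bin is a peak apex iff it is the
#' strict maximum of its `+/- halfwindow` neighbourhood and its intensity
#' exceeds `mad_k` times the noise estimate.
#'
#' @param x Spectrum vector.
#' @param mad_k SNR threshold multiplier.
#' @param halfwindow Neighbourhood half-width in bins (< `length(x)`).
#' @param mz Optional m/z axis (e.g. [bin_centers()]); apex positions are
#'   reported on it, otherwise as bin indices.
#' @return A [peak_list()] in increasing m/z order.
#' @export
detect_peaks_mad <- function(x, mad_k = 3, halfwindow = 20L, mz = NULL) {
  n <- length(x)
  if (halfwindow >= n) stop("halfwindow must be smaller than the spectrum length")
  if (any(!is.finite(x))) stop("spectrum must be finite")
  noise <- 1.4826 * stats::median(abs(x - stats::median(x)))
  thr <- mad_k * noise
  cand <- which(x > thr)
  apex <- logical(n)
  for (i in cand) {
    w <- max(1L, i - halfwindow):min(n, i + halfwindow)
    w <- w[w != i]
    if (all(x[i] > x[w])) apex[i] <- TRUE
  }
  idx <- which(apex)
  pos <- if (is.null(mz)) idx else mz[idx]
  peak_list(pos, x[idx], snr = if (noise > 0) x[idx] / noise else rep(Inf, length(idx)))
}

#' Greedy one-to-one peak matching
#'
#' Matches observed peaks to reference peaks by increasing distance: the
#' closest available pair within `tolerance` is matched first and each peak
#' is used at most once (so of two candidates near one reference, the closer
#' wins).
#'
#' @param peaks,reference [peak_list()]s.
#' @param tolerance Maximum matching distance, Da.
#' @return Data frame with columns `observed`, `reference`, `obs_intensity`,
#'   `ref_intensity`, `distance` (possibly zero rows).
#' @export
match_reference_peaks <- function(peaks, reference, tolerance = 0.5) {
  if (tolerance <= 0) stop("tolerance must be positive")
  empty <- data.frame(observed = numeric(0), reference = numeric(0),
                      obs_intensity = numeric(0), ref_intensity = numeric(0),
                      distance = numeric(0))
  if (length(peaks) == 0 || length(reference) == 0) return(empty)
  d <- abs(outer(peaks$apex_mz, reference$apex_mz, "-"))
  pairs <- which(d <= tolerance, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(empty)
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used_p <- logical(length(peaks)); used_r <- logical(length(reference))
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!used_p[i] && !used_r[j]) {
      used_p[i] <- TRUE; used_r[j] <- TRUE; keep[r] <- TRUE
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  out <- data.frame(observed = peaks$apex_mz[pairs[, 1]],
                    reference = reference$apex_mz[pairs[, 2]],
                    obs_intensity = peaks$apex_intensity[pairs[, 1]],
                    ref_intensity = reference$apex_intensity[pairs[, 2]],
                    distance = d[pairs])
  out[order(out$observed), , drop = FALSE]
}

#' Fit a cubic warping function by weighted least squares
#'
#' Estimates the coefficients of the cubic warp
#' `w(x) = a0 + a1 x + a2 x^2 + a3 x^3` minimising the weighted squared
#' offsets `sum w_i (reference_i - w(observed_i))^2`. Weights default to the
#' matched reference peak intensities (heavier peaks trusted more); pass unit
#' weights to disable. A warning is issued if the fitted warp is not strictly
#' increasing over the fitted range.
#'
#' @param observed,reference Matched peak positions (>= 4 distinct observed
#'   values), e.g. columns of [match_reference_peaks()].
#' @param weights Positive weights (default the `ref_intensity` attribute is
#'   NOT assumed — supply explicitly, or unit weights are used).
#' @return An object of class `warp_model`: coefficients `alpha` (a0..a3),
#'   fitted `residuals` and the weighted residual sum of squares `wrss`.
#' @export
fit_cubic_warp <- function(observed, reference, weights = NULL) {
  if (length(observed) != length(reference))
    stop("observed and reference must have equal length")
  if (length(unique(observed)) < 4)
    stop("at least 4 pairs with distinct observed positions are required")
  if (is.null(weights)) weights <- rep(1, length(observed))
  if (any(weights <= 0)) stop("weights must be positive")
  X <- cbind(1, observed, observed^2, observed^3)
  qrX <- qr(X * sqrt(weights))
  if (qrX$rank < 4)
    stop("singular design: observed positions are collinear to cubic degeneracy")
  fit <- stats::lm.wfit(X, reference, w = weights)
  alpha <- unname(fit$coefficients)
  res <- reference - drop(X %*% alpha)
  w <- structure(list(alpha = alpha, residuals = res,
                      wrss = sum(weights * res^2),
                      range = range(observed)),
                 class = "warp_model")
  xs <- seq(w$range[1], w$range[2], length.out = 201)
  if (any(diff(warp_apply(w, xs)) <= 0))
    warning("fitted warp is not strictly increasing over the fitted range")
  w
}

#' @export
print.warp_model <- function(x, ...) {
  cat(sprintf("<warp_model> w(x) = %.6g + %.6g x + %.3g x^2 + %.3g x^3 (wrss %.3g)\n",
              x$alpha[1], x$alpha[2], x$alpha[3], x$alpha[4], x$wrss))
  invisible(x)
}

#' Evaluate a warp polynomial
#' @param warp A `warp_model` (or numeric length-4 coefficient vector).
#' @param x Positions in Da.
#' @return Warped positions `w(x)`.
#' @export
warp_apply <- function(warp, x) {
  a <- if (inherits(warp, "warp_model")) warp$alpha else warp
  a[1] + a[2] * x + a[3] * x^2 + a[4] * x^3
}

#' Warp the m/z axis of a raw spectrum
#'
#' Maps the m/z axis through the warp polynomial, leaving intensities
#' unchanged. If the warp is non-monotone over the spectrum's range a warning
#' is issued and the output is re-sorted.
#'
#' @param raw A [raw_spectrum()].
#' @param warp A `warp_model` or coefficient vector.
#' @return A [raw_spectrum()] on the warped axis.
#' @export
apply_warp <- function(raw, warp) {
  mz <- warp_apply(warp, raw$mz)
  intensity <- raw$intensity
  if (any(diff(mz) <= 0)) {
    warning("warp is not monotone over the spectrum range; re-sorting")
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    keep <- c(TRUE, diff(mz) > 0)
    mz <- mz[keep]; intensity <- intensity[keep]
  }
  raw_spectrum(mz, intensity, id = raw$id)
}

#' Align the spectra of each class to their class reference
#'
#' Per class (classes are never mixed): the reference peak list is detected
#' on the class-average spectrum; each member spectrum's peaks are matched to
#' it, a weighted cubic warp is fitted (reference intensities as weights) and
#' the member is re-binned on the warped axis. Members with fewer than 4
#' matches, and classes with a single spectrum, pass through unchanged with a
#' warning.
#'
#' @param ds A binned [spectra_dataset()].
#' @param config A [preprocess_config()].
#' @return List with `dataset` (aligned [spectra_dataset()]), `warps` (list
#'   of per-spectrum `warp_model`s or `NULL`) and `references` (per-class
#'   [peak_list()]s).
#' @export
align_by_class <- function(ds, config = preprocess_config()) {
  centers <- bin_centers(ds$grid)
  m <- ds$matrix
  warps <- vector("list", nrow(m))
  refs <- vector("list", length(ds$class_names))
  names(refs) <- ds$class_names
  for (cl in sort(unique(ds$labels))) {
    rows <- which(ds$labels == cl)
    if (length(rows) < 2) {
      warning(sprintf("class '%s' has a single spectrum; passed through unaligned",
                      ds$class_names[cl]))
      next
    }
    ref_spec <- colMeans(m[rows, , drop = FALSE])
    ref <- detect_peaks_mad(ref_spec, config$mad_k, config$halfwindow,
                            mz = centers)
    refs[[cl]] <- ref
    for (r in rows) {
      pk <- detect_peaks_mad(m[r, ], config$mad_k, config$halfwindow,
                             mz = centers)
      matched <- match_reference_peaks(pk, ref, config$match_tolerance)
      if (nrow(matched) >= 4 && length(unique(matched$observed)) >= 4) {
        w <- fit_cubic_warp(matched$observed, matched$reference,
                            weights = matched$ref_intensity)
        warped <- apply_warp(raw_spectrum(centers, m[r, ]), w)
        m[r, ] <- bin_spectrum(warped, ds$grid, aggregate = "sum")
        warps[[r]] <- w
      }
    }
  }
  out <- ds
  out$matrix <- m
  list(dataset = out, warps = warps, references = refs)
}

#' The five-step conventional preprocessing pipeline
#'
#' Applies, in order: (1) log-intensity transform, (2) SNIP baseline
#' subtraction, (3) TIC normalisation, (4) per-class cubic-warp alignment,
#' (5) MAD peak detection on the aligned class-average spectra. The feature
#' matrix holds the aligned, normalised intensities at the union of the
#' detected per-class reference peak bins, giving every spectrum the same
#' fixed-width feature vector.
#'
#' @param ds A binned [spectra_dataset()].
#' @param config A [preprocess_config()].
#' @param order Step order (any permutation of the five step names; the
#'   default is the canonical enumeration).
#' @return An object of class `preprocess_result`: `features`
#'   (n_spectra x n_peaks matrix), `feature_mz` (bin centres of the selected
#'   peaks), `dataset` (fully processed spectra), `references` (per-class
#'   reference [peak_list()]s) and `warps`.
#' @export
preprocess_pipeline <- function(ds, config = preprocess_config(),
                                order = c("log", "snip", "tic", "align", "detect")) {
  stopifnot(setequal(order, c("log", "snip", "tic", "align", "detect")))
  m <- ds$matrix
  warps <- NULL
  refs <- NULL
  for (step in order) {
    if (step == "log") {
      m <- t(apply(m, 1, log_transform, offset = config$log_offset))
    } else if (step == "snip") {
      m <- t(apply(m, 1, function(x) x - snip_baseline(x, config$snip_iterations)))
    } else if (step == "tic") {
      m <- t(apply(m, 1, tic_normalize))
    } else if (step == "align") {
      tmp <- ds; tmp$matrix <- m
      al <- align_by_class(tmp, config)
      m <- al$dataset$matrix
      warps <- al$warps
      refs <- al$references
    } else if (step == "detect") {
      if (is.null(refs)) {  # detect without a preceding align step
        centers <- bin_centers(ds$grid)
        refs <- lapply(sort(unique(ds$labels)), function(cl) {
          detect_peaks_mad(colMeans(m[ds$labels == cl, , drop = FALSE]),
                           config$mad_k, config$halfwindow, mz = centers)
        })
        names(refs) <- ds$class_names
      }
    }
  }
  feature_mz <- sort(unique(unlist(lapply(refs, function(p)
    if (is.null(p)) numeric(0) else p$apex_mz))))
  bins <- .bin_index(feature_mz, ds$grid)
  out_ds <- ds; out_ds$matrix <- m
  structure(list(features = m[, bins, drop = FALSE], feature_mz = feature_mz,
                 feature_bins = bins, dataset = out_ds, references = refs,
                 warps = warps),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat(sprintf("<preprocess_result> %d spectra, %d peak features\n",
              nrow(x$features), ncol(x$features)))
  invisible(x)
}
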