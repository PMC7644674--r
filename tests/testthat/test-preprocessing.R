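test_that("log transform is anchored at zero and monotone", {
  expect_equal(log_transform(0, offset = 1), 0)
  expect_equal(log_transform(c(0, exp(1) - 1), offset = 1), c(0, 1))
  x <- sort(runif(50, 0, 100))
  expect_true(all(diff(log_transform(x)) > 0))
  expect_error(log_transform(-1), "non-negative")
})

test_that("SNIP baseline clips from below and preserves flat regions", {
  # constant spectrum: baseline equals the signal, residual zero
  x <- rep(5, 100)
  b <- snip_baseline(x, 10)
  expect_equal(b, x, tolerance = 1e-9)

  # independent literal small-vector oracle (LLS + expanding clip)
  set.seed(4)
  x <- 10 + runif(80)
  x[38:40] <- x[38:40] + 100
  snip_oracle <- function(x, iters) {
    v <- log(log(sqrt(x + 1) + 1) + 1)
    n <- length(x)
    for (m in seq_len(iters)) {
      w <- v
      for (i in (m + 1):(n - m)) w[i] <- min(v[i], (v[i - m] + v[i + m]) / 2)
      v <- w
    }
    pmin((exp(exp(v) - 1) - 1)^2 - 1, x)
  }
  b <- snip_baseline(x, 20)
  expect_equal(b, snip_oracle(x, 20), tolerance = 1e-9)

  # the spike survives in the residual; the baseline hugs the flat level
  residual <- x - b
  expect_gte(max(residual[38:40]), 0.9 * 100)
  away <- c(10:30, 50:70)
  expect_true(all(abs(b[away] - 10) / 10 < 0.05))

  # clipping property on random spectra
  for (r in 1:5) {
    x <- runif(60, 0, 50)
    b <- snip_baseline(x, 12)
    expect_true(all(b <= x + 1e-12))
    expect_true(all(x - b >= -1e-12))
  }
  expect_error(snip_baseline(runif(10), 5), "half")
})

test_that("TIC normalisation produces unit-sum, scale-invariant spectra", {
  expect_equal(tic_normalize(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  x <- runif(100)
  expect_lt(abs(sum(tic_normalize(x)) - 1), 1e-12)
  expect_equal(tic_normalize(7 * x), tic_normalize(x))
  expect_error(tic_normalize(rep(0, 5)), "all-zero")
})

test_that("MAD peak detection matches the hand-computed oracle", {
  # constant spectrum: MAD = 0 and no strict maxima
  expect_length(detect_peaks_mad(rep(3, 50), 3, 5), 0)

  # single nonzero bin
  x <- rep(0, 50); x[25] <- 100
  pk <- detect_peaks_mad(x, 3, 5)
  expect_equal(pk$apex_mz, 25)
  expect_equal(pk$apex_intensity, 100)

  # printed toy vector: median 1, MAD 0, apexes at the two strict maxima
  x <- c(1, 1, 9, 1, 1, 1, 7, 1)
  pk <- detect_peaks_mad(x, mad_k = 3, halfwindow = 2)
  expect_equal(pk$apex_mz, c(3, 7))  # 1-based positions of values 9 and 7

  # the MAD threshold suppresses sub-threshold maxima
  set.seed(8)
  x <- abs(rnorm(200))
  x[100] <- 50
  noise <- 1.4826 * median(abs(x - median(x)))
  pk <- detect_peaks_mad(x, mad_k = 3, halfwindow = 10)
  expect_true(all(pk$apex_intensity > 3 * noise))
  expect_true(100 %in% pk$apex_mz)
  expect_error(detect_peaks_mad(x, 3, 300), "halfwindow")
})

test_that("peak matching is greedy, one-to-one and tolerance-bounded", {
  a <- peak_list(c(100, 105, 110), c(1, 2, 3))
  m <- match_reference_peaks(a, a, tolerance = 0.5)
  expect_equal(nrow(m), 3)
  expect_true(all(m$distance == 0))

  b <- peak_list(c(200, 300), c(1, 1))
  expect_equal(nrow(match_reference_peaks(a, b, 0.5)), 0)

  # two observed candidates near one reference: the closer one wins
  obs <- peak_list(c(100.1, 100.3), c(1, 1))
  ref <- peak_list(100, 1)
  m <- match_reference_peaks(obs, ref, tolerance = 0.5)
  expect_equal(nrow(m), 1)
  expect_equal(m$observed, 100.1)
})

test_that("cubic warp fitting recovers generating coefficients", {
  # identity
  x <- seq(100, 200, length.out = 12)
  w <- fit_cubic_warp(x, x)
  expect_lt(max(abs(w$alpha - c(0, 1, 0, 0))), 1e-9)

  # closed-form weighted LS oracle via the normal equations
  alpha_true <- c(5.0, 1.001, 1e-6, -1e-10)
  x <- seq(100, 2000, length.out = 10)
  y <- alpha_true[1] + alpha_true[2] * x + alpha_true[3] * x^2 + alpha_true[4] * x^3
  w <- fit_cubic_warp(x, y)
  expect_lt(max(abs(w$alpha - alpha_true) / pmax(abs(alpha_true), 1e-12)), 1e-6)

  X <- cbind(1, x, x^2, x^3)
  wt <- runif(10, 0.5, 2)
  yn <- y + rnorm(10, 0, 0.01)
  oracle <- qr.solve(sqrt(wt) * X, sqrt(wt) * yn)   # closed-form WLS
  w2 <- fit_cubic_warp(x, yn, weights = wt)
  expect_lt(max(abs(w2$alpha - oracle)), 1e-6)

  expect_error(fit_cubic_warp(x[1:3], y[1:3]), "4 pairs")
})

test_that("warping maps the axis and round-trips through the inverse fit", {
  raw <- raw_spectrum(seq(100, 110, 0.5), runif(21))
  same <- apply_warp(raw, c(0, 1, 0, 0))
  expect_equal(same$mz, raw$mz)
  expect_equal(same$intensity, raw$intensity)

  shifted <- apply_warp(raw, c(1, 1, 0, 0))
  expect_equal(shifted$mz, raw$mz + 1)

  # fit on swapped pairs gives the inverse map
  a <- c(0.5, 1.0005, 1e-7, 0)
  x <- seq(100, 400, length.out = 20)
  y <- warp_apply(a, x)
  inv <- fit_cubic_warp(y, x)
  expect_lt(max(abs(warp_apply(inv, y) - x)), 1e-6)
})

test_that("per-class alignment recovers a simulated linear shift", {
  grid <- bin_grid(100, 200, 0.1)
  tpl <- class_template(c(115.03, 130.07, 148.02, 163.04, 181.05),
                        c(1, 0.8, 0.9, 0.6, 1), 0.3)
  base <- synthesize_spectrum(tpl, quiet_noise(), grid, seed = 1)
  v0 <- bin_spectrum(base, grid)
  shifted <- raw_spectrum(base$mz + 0.5, base$intensity)
  v1 <- bin_spectrum(shifted, grid)
  m <- rbind(v0, v0, v1, v1)
  ds <- spectra_dataset(m, rep(1, 4), "a", grid)
  al <- align_by_class(ds, preprocess_config(halfwindow = 10,
                                             match_tolerance = 1))
  centers <- bin_centers(grid)
  ref <- detect_peaks_mad(colMeans(al$dataset$matrix), 3, 10, mz = centers)
  offs <- sapply(seq_len(4), function(r) {
    pk <- detect_peaks_mad(al$dataset$matrix[r, ], 3, 10, mz = centers)
    mm <- match_reference_peaks(pk, ref, 1)
    mean(abs(mm$observed - mm$reference))
  })
  expect_lt(mean(offs), 0.1)
  expect_equal(nrow(al$dataset$matrix), 4)

  # already-aligned class: warps stay near the identity
  m2 <- rbind(v0, v0, v0)
  ds2 <- spectra_dataset(m2, rep(1, 3), "a", grid)
  al2 <- align_by_class(ds2, preprocess_config(halfwindow = 10,
                                               match_tolerance = 1))
  for (w in al2$warps) {
    if (is.null(w)) next
    expect_lt(sqrt(sum((w$alpha - c(0, 1, 0, 0))^2)), 1e-3)
  }
})

test_that("alignment preserves total ion count of interior spectra", {
  grid <- bin_grid(100, 200, 0.1)
  tpl <- class_template(c(120.03, 140.07, 160.02, 180.04), rep(1, 4), 0.3)
  base <- synthesize_spectrum(tpl, quiet_noise(), grid, seed = 2)
  v0 <- bin_spectrum(base, grid)
  shifted <- raw_spectrum(base$mz + 0.3, base$intensity)
  v1 <- bin_spectrum(shifted, grid)
  ds <- spectra_dataset(rbind(v0, v1, v0), rep(1, 3), "a", grid)
  tic_before <- rowSums(ds$matrix)
  al <- align_by_class(ds, preprocess_config(halfwindow = 10, match_tolerance = 1))
  tic_after <- rowSums(al$dataset$matrix)
  expect_equal(tic_after, tic_before, tolerance = 1e-6)
})

test_that("the five-step pipeline yields non-negative peak features at template positions", {
  grid <- bin_grid(100, 200, 0.1)
  spec <- task_spec(grid, n_per_class = 8,
                    noise = noise_model(shift_sd = 0.05, intensity_cv = 0.05,
                                        baseline_amp = 0.3,
                                        baseline_decay = 0.01,
                                        noise_sd = 0.002, dropout_p = 0),
                    shared_fraction = 0, n_peaks = 4, peak_width = 0.3,
                    amp_range = c(0.5, 1), seed = 77)
  ds <- generate_task(spec)
  tpl <- attr(ds, "templates")[[1]]
  res <- preprocess_pipeline(ds, preprocess_config(halfwindow = 10,
                                                   match_tolerance = 1))
  expect_gte(ncol(res$features), length(tpl$peak_mz))
  expect_true(all(res$features >= 0))
  for (p in tpl$peak_mz)
    expect_true(min(abs(res$feature_mz - p)) < 0.5)

  res2 <- preprocess_pipeline(ds, preprocess_config(halfwindow = 10,
                                                    match_tolerance = 1))
  expect_identical(res$features, res2$features)
})
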