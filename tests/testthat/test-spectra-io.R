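test_that("bin counts follow the grid arithmetic", {
  expect_identical(n_bins(100, 1600, 0.1), 15000L)
  expect_identical(n_bins(100, 2000, 0.1), 19000L)
  expect_identical(n_bins(0, 10, 1), 10L)
  expect_error(n_bins(100, 100, 0.1), "mass range")
  expect_error(n_bins(100, 200, 0), "positive")
  expect_error(n_bins(100, 50, 0.1), "mass range")
})

test_that("binning places points in half-open bins and conserves intensity", {
  grid <- bin_grid(100, 1600, 0.1)
  v <- bin_spectrum(raw_spectrum(100.05, 7.0), grid)
  expect_equal(v[1], 7.0)
  expect_equal(sum(v), 7.0)

  # a point exactly on a bin edge belongs to the upper bin
  v <- bin_spectrum(raw_spectrum(100.1, 1.0), grid)
  expect_equal(which(v > 0), 2L)

  # a point at mass_max is dropped
  v <- bin_spectrum(raw_spectrum(1600, 3.0), grid)
  expect_equal(sum(v), 0)
  expect_equal(attr(v, "n_dropped"), 1L)

  # conservation for an arbitrary in-range spectrum, plus n_bins consistency
  set.seed(1)
  for (r in 1:5) {
    mz <- sort(runif(200, 100, 1599.9))
    mz <- mz[c(TRUE, diff(mz) > 0)]
    it <- runif(length(mz), 0, 10)
    v <- bin_spectrum(raw_spectrum(mz, it), grid, aggregate = "sum")
    expect_length(v, grid$n_bins)
    expect_lt(abs(sum(v) - sum(it)) / sum(it), 1e-9)
  }
})

test_that("binning aggregates mean and max per bin", {
  grid <- bin_grid(0, 10, 1)
  raw <- raw_spectrum(c(0.2, 0.7, 5.5), c(2, 4, 8))
  expect_equal(bin_spectrum(raw, grid, "mean")[1], 3)
  expect_equal(bin_spectrum(raw, grid, "max")[1], 4)
  expect_equal(bin_spectrum(raw, grid, "sum")[6], 8)
})

test_that("raw spectra validate ordering and non-negativity", {
  expect_error(raw_spectrum(c(1, 2), c(1, 2, 3)), "same length")
  expect_error(raw_spectrum(c(2, 1), c(1, 1)), "increasing")
  expect_error(raw_spectrum(c(1, 2), c(-1, 1)), "non-negative")
})

test_that("unit-interval scaling is row-wise with a zero convention", {
  grid <- bin_grid(0, 3, 1)
  m <- rbind(c(2, 4, 6), c(5, 5, 5), c(0, 1, 3))
  ds <- spectra_dataset(m, c(1, 1, 2), c("a", "b"), grid)
  s <- scale_unit_interval(ds)
  expect_true(s$scaled)
  expect_equal(s$matrix[1, ], c(0, 0.5, 1))
  expect_equal(s$matrix[2, ], c(0, 0, 0))
  expect_equal(min(s$matrix[3, ]), 0)
  expect_equal(max(s$matrix[3, ]), 1)

  g <- scale_unit_interval(ds, per = "dataset")
  expect_equal(max(g$matrix), 1)
  expect_equal(min(g$matrix), 0)
})

test_that("stratified splits are disjoint, exhaustive and proportion-preserving", {
  labels <- rep(c(1, 2), each = 10)
  sp <- stratified_split(labels, c(0.6, 0.2, 0.2), seed = 3)
  expect_equal(sort(c(sp$train, sp$validation, sp$test)), 1:20)
  for (cl in 1:2) {
    expect_equal(sum(labels[sp$train] == cl), 6)
    expect_equal(sum(labels[sp$validation] == cl), 2)
    expect_equal(sum(labels[sp$test] == cl), 2)
  }
  sp2 <- stratified_split(labels, c(0.6, 0.2, 0.2), seed = 3)
  expect_identical(sp, sp2)

  # uneven class sizes stay within one sample of the target per subset
  labels <- rep(1:3, c(17, 11, 7))
  sp <- stratified_split(labels, seed = 9)
  for (cl in 1:3) {
    n_c <- sum(labels == cl)
    expect_lte(abs(sum(labels[sp$train] == cl) - 0.6 * n_c), 1)
    expect_lte(abs(sum(labels[sp$test] == cl) - 0.2 * n_c), 1)
  }

  expect_error(stratified_split(labels, c(0.5, 0.2, 0.2)), "sum to 1")
  expect_warning(stratified_split(c(1, 1, 1, 2), seed = 1), "fewer than 3")
})

test_that("a small minority class is always represented in the test set", {
  labels <- rep(c(1, 2), c(50, 5))
  for (seed in 1:1000) {
    sp <- stratified_split(labels, seed = seed)
    expect_equal(sum(labels[sp$test] == 2), 1)
  }
})

test_that("spectrum similarity matches the textbook formulas", {
  a <- c(1, 2, 3); b <- c(3, 2, 1)
  expect_equal(spectrum_similarity(a, a, "pearson"), 1.0)
  expect_equal(spectrum_similarity(a, a, "cosine"), 1.0)
  expect_equal(spectrum_similarity(a, b, "pearson"), -1.0)
  expect_equal(spectrum_similarity(c(1, 0), c(0, 1), "cosine"), 0.0)

  # two-pass formula oracle on random vectors
  set.seed(7)
  for (r in 1:20) {
    n <- sample(3:100, 1)
    x <- rnorm(n); y <- rnorm(n)
    pearson_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    cosine_oracle <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    expect_lt(abs(spectrum_similarity(x, y, "pearson") - pearson_oracle), 1e-12)
    expect_lt(abs(spectrum_similarity(x, y, "cosine") - cosine_oracle), 1e-12)
  }

  expect_error(spectrum_similarity(c(1, 1), c(1, 2), "pearson"), "constant")
  expect_error(spectrum_similarity(c(0, 0), c(1, 2), "cosine"), "zero")
  expect_error(spectrum_similarity(1, 1), "length")
})

test_that("wide CSV round-trips losslessly", {
  grid <- bin_grid(100, 100.5, 0.1)
  m <- matrix(runif(15), 3, 5)
  ds <- spectra_dataset(m, c(1, 2, 1), c("healthy", "tumour"), grid,
                        sample_ids = c("s1", "s2", "s3"))
  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f, "wide_csv")
  back <- read_dataset(f, "wide_csv")
  expect_equal(back$matrix, ds$matrix, tolerance = 1e-12)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$class_names, ds$class_names)
  expect_equal(back$grid$n_bins, ds$grid$n_bins)
  unlink(f)
})

test_that("long CSV round-trips and rejects malformed input", {
  spectra <- list(raw_spectrum(c(100, 101, 102), c(1, 5, 2), id = "a"),
                  raw_spectrum(c(100.5, 101.5), c(3, 4), id = "b"))
  attr(spectra, "labels") <- c("x", "y")
  f <- tempfile(fileext = ".csv")
  write_dataset(spectra, f, "long_csv")
  back <- read_dataset(f, "long_csv")
  expect_equal(back[[1]]$mz, spectra[[1]]$mz)
  expect_equal(back[[2]]$intensity, spectra[[2]]$intensity)
  expect_equal(attr(back, "labels"), c("x", "y"))

  writeLines(c("spectrum_id,label,mz,intensity",
               "a,x,101,1", "a,x,100,2"), f)
  expect_error(read_dataset(f, "long_csv"), "unsorted")

  writeLines(c("spectrum_id,label,mz,intensity",
               "a,x,100,1", "a,x,101,-2"), f)
  expect_error(read_dataset(f, "long_csv"), "negative")
  unlink(f)
})

test_that("wide CSV reader reports offending rows", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,label,mz_100.05,mz_100.15",
               "s1,a,1,2", "s2,b,3,-1"), f)
  expect_error(read_dataset(f, "wide_csv"), "row 2")
  unlink(f)
})
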