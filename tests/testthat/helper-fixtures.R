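# Shared fixtures: everything is generated in code at test time.

# a small grid used across tests: 100-120 Da at 0.1 Da -> 200 bins
small_grid <- function() bin_grid(100, 120, 0.1)

# a quiet noise model for near-deterministic spectra
quiet_noise <- function() {
  noise_model(shift_sd = 0, intensity_cv = 0, baseline_amp = 0,
              baseline_decay = 0, noise_sd = 0, dropout_p = 0)
}

# a tiny, well-separated two-class task (high SNR, disjoint peaks)
separable_task <- function(n_per_class = c(30, 30), seed = 42) {
  task_spec(small_grid(), n_per_class = n_per_class,
            noise = noise_model(shift_sd = 0.05, intensity_cv = 0.1,
                                baseline_amp = 0.1, baseline_decay = 0.01,
                                noise_sd = 0.005, dropout_p = 0),
            shared_fraction = 0, n_peaks = 5, peak_width = 0.15,
            amp_range = c(0.4, 1), seed = seed)
}

# small architecture fitting a 200-bin input (for engine tests)
tiny_arch <- function(n_classes = 2, input_length = 200) {
  build_architecture("variant_lecun", input_length, n_classes,
                     filters = c(4, 8), kernels = c(9, 5), dense_units = 16)
}

# reduced-scale task family mirroring the package's default study conditions
small_family <- function(seed = 1) {
  default_task_family(seed = seed, n_source_per_class = 120, n_12class = 8,
                      n_5class = 10, n_2class = 40)
}

expect_all_equal <- function(a, b, tol = 1e-12) {
  expect_true(max(abs(a - b)) <= tol)
}
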