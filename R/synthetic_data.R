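#' Class template: the idealised spectrum of one class
#'
#' A set of Gaussian peaks (position, amplitude, width) that defines what a
#' noise-free member of the class looks like. Per-spectrum variability
#' (position jitter, intensity fluctuation, baseline, noise, peak dropout) is
#' layered on top by a [noise_model()].
#'
#' @param peak_mz Peak positions in Da.
#' @param peak_amp Positive peak amplitudes (arbitrary intensity units).
#' @param peak_width Gaussian sigma per peak, Da (recycled if scalar).
#' @param class_name Class label.
#' @return An object of class `class_template`.
#' @export
class_template <- function(peak_mz, peak_amp, peak_width, class_name = "class") {
  if (any(peak_amp <= 0)) stop("amplitudes must be positive")
  if (any(peak_width <= 0)) stop("widths must be positive")
  o <- order(peak_mz)
  structure(list(peak_mz = as.numeric(peak_mz[o]),
                 peak_amp = as.numeric(peak_amp[o]),
                 peak_width = rep_len(as.numeric(peak_width), length(peak_mz))[o],
                 class_name = class_name),
            class = "class_template")
}

#' Per-spectrum variability model
#'
#' The technical-variation structure of profile MS acquisitions: additive
#' jitter on every peak position (instrument calibration drift), multiplicative
#' log-normal intensity fluctuation, an exponentially decaying additive
#' baseline, additive Gaussian noise clipped at zero, and random peak dropout.
#'
#' @param shift_sd Per-spectrum peak-position jitter SD, Da.
#' @param intensity_cv Coefficient of variation of the per-peak multiplicative
#'   log-normal amplitude factor (mean-preserving).
#' @param baseline_amp Baseline amplitude at the low-mass edge, intensity units.
#' @param baseline_decay Baseline exponential decay rate, 1/Da:
#'   `baseline_amp * exp(-baseline_decay * (mz - mass_min))`.
#' @param noise_sd Additive Gaussian noise SD, intensity units.
#' @param dropout_p Probability that any given peak is absent from a spectrum.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(shift_sd = 0.2, intensity_cv = 0.35,
                        baseline_amp = 0.3, baseline_decay = 0.01,
                        noise_sd = 0.02, dropout_p = 0.05) {
  vals <- c(shift_sd, intensity_cv, baseline_amp, baseline_decay, noise_sd, dropout_p)
  if (any(vals < 0)) stop("noise parameters must be non-negative")
  if (dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  structure(list(shift_sd = shift_sd, intensity_cv = intensity_cv,
                 baseline_amp = baseline_amp, baseline_decay = baseline_decay,
                 noise_sd = noise_sd, dropout_p = dropout_p),
            class = "noise_model")
}

#' Specification of one synthetic classification task
#'
#' @param grid A [bin_grid()].
#' @param templates List of [class_template()]s (or `NULL` to have
#'   [generate_task()] build them via [make_templates()]).
#' @param n_per_class Integer vector of spectra counts per class; imbalance is
#'   first-class here, mirroring real clinical tables.
#' @param noise A [noise_model()].
#' @param shared_fraction Fraction of peak positions shared by all classes
#'   ("housekeeping" signal), used when templates are built internally.
#' @param n_peaks Peaks per class when templates are built internally.
#' @param peak_width Gaussian sigma used for internally built templates, Da.
#' @param amp_range,class_amp_sd,specific_amp_range Template amplitude
#'   parameters, see [make_templates()].
#' @param seed Integer seed; expands to per-spectrum substreams so generation
#'   order cannot change results.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(grid, templates = NULL, n_per_class, noise = noise_model(),
                      shared_fraction = 0.5, n_peaks = 20,
                      peak_width = 1.5 * grid$bin_width,
                      amp_range = c(0.05, 1), class_amp_sd = 0.5,
                      specific_amp_range = amp_range, seed = 1L) {
  if (!is.null(templates) && length(templates) != length(n_per_class))
    stop("length(n_per_class) must equal the number of templates")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]")
  structure(list(grid = grid, templates = templates,
                 n_per_class = as.integer(n_per_class), noise = noise,
                 shared_fraction = shared_fraction, n_peaks = as.integer(n_peaks),
                 peak_width = peak_width, amp_range = amp_range,
                 class_amp_sd = class_amp_sd,
                 specific_amp_range = specific_amp_range,
                 seed = as.integer(seed)),
            class = "task_spec")
}

# Deterministic substream seed for spectrum k of a task seeded with `seed`.
.substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483629 * 1000003 + k) %% 2147483629)
}

# Draw `n` peak positions with a minimum separation inside the grid
# (sampled from a jittered lattice, so separation is guaranteed).
.draw_positions <- function(n, grid, min_sep, exclude = numeric(0)) {
  margin <- 4 * min_sep / 3
  lattice <- seq(grid$mass_min + margin, grid$mass_max - margin, by = min_sep)
  if (length(exclude))
    lattice <- lattice[vapply(lattice, function(p) all(abs(p - exclude) >= min_sep / 2), logical(1))]
  if (n > length(lattice))
    stop("too many peaks requested for this grid at the required separation")
  sort(sample(lattice, n))
}

#' Build class templates with shared and class-specific peaks
#'
#' Each of `n_classes` templates carries `n_peaks` Gaussian peaks;
#' `floor(shared_fraction * n_peaks)` positions are common to all classes
#' (housekeeping signal) and the remainder are class-specific. Amplitudes are
#' log-uniform in `amp_range`. Reproducible for a fixed seed.
#'
#' @inheritParams task_spec
#' @param n_classes Number of classes.
#' @param amp_range Amplitude range of the shared peaks' base amplitudes
#'   (log-uniform sampling).
#' @param class_amp_sd SD of the per-class log-normal effect multiplying each
#'   shared peak's base amplitude: classes differ on housekeeping peaks by
#'   intensity ratios rather than presence/absence, as in real tissue
#'   spectra.
#' @param specific_amp_range Amplitude range of the class-specific peaks
#'   (defaults to `amp_range`); small values emulate discriminative signals
#'   of low intensity sitting close to the baseline noise.
#' @param min_separation Minimum distance between any two peak positions, Da.
#' @param position_pool Optional vector of candidate positions the
#'   class-specific peaks are drawn from (used to link tasks of a family);
#'   `NULL` draws fresh positions.
#' @param shared_pool Optional candidate positions for the shared peaks.
#' @param exclude Positions whose neighbourhood freshly drawn class-specific
#'   peaks must avoid.
#' @return List of [class_template()]s.
#' @export
make_templates <- function(n_classes, n_peaks, shared_fraction, grid, seed,
                           peak_width = 1.5 * grid$bin_width,
                           amp_range = c(0.05, 1),
                           class_amp_sd = 0.5,
                           specific_amp_range = amp_range,
                           min_separation = max(8 * peak_width, 4 * grid$bin_width),
                           position_pool = NULL, shared_pool = NULL,
                           exclude = numeric(0)) {
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  if (n_peaks > grid$n_bins) stop("n_peaks exceeds the number of bins")
  n_shared <- floor(shared_fraction * n_peaks)
  n_spec <- n_peaks - n_shared
  with_seed(seed, {
    shared <- if (n_shared > 0) {
      if (is.null(shared_pool)) .draw_positions(n_shared, grid, min_separation)
      else sort(sample(shared_pool, n_shared))
    } else numeric(0)
    shared_base <- exp(stats::runif(n_shared, log(amp_range[1]),
                                    log(amp_range[2])))
    specific <- if (n_spec > 0) {
      if (is.null(position_pool)) {
        pos <- .draw_positions(n_spec * n_classes, grid, min_separation,
                               exclude = c(shared, exclude))
        split(sample(pos), rep(seq_len(n_classes), each = n_spec))
      } else {
        pos <- sample(position_pool, n_spec * n_classes)
        split(pos, rep(seq_len(n_classes), each = n_spec))
      }
    } else rep(list(numeric(0)), n_classes)
    lapply(seq_len(n_classes), function(cl) {
      amp_shared <- shared_base * exp(stats::rnorm(n_shared, 0, class_amp_sd))
      amp_spec <- exp(stats::runif(length(specific[[cl]]),
                                   log(specific_amp_range[1]),
                                   log(specific_amp_range[2])))
      class_template(c(shared, specific[[cl]]),
                     peak_amp = c(amp_shared, amp_spec),
                     peak_width = peak_width,
                     class_name = paste0("class", cl))
    })
  })
}

#' Synthesise one raw profile spectrum from a template
#'
#' The profile is laid on a dense m/z axis at one fifth of the task bin width
#' (so that sub-bin position jitter produces realistic bin-level
#' misalignment), as the sum of the surviving template peaks (Gaussians at
#' jittered positions with log-normally perturbed amplitudes), an exponential
#' baseline, and zero-clipped additive Gaussian noise.
#'
#' @param template A [class_template()].
#' @param noise A [noise_model()].
#' @param grid The task [bin_grid()] (sets the dense axis resolution).
#' @param seed Optional integer; `NULL` uses the current RNG stream.
#' @param id Spectrum identifier.
#' @return A [raw_spectrum()] (non-negative everywhere).
#' @export
synthesize_spectrum <- function(template, noise, grid, seed = NULL,
                                id = "synthetic") {
  gen <- function() {
    dw <- grid$bin_width / 5
    n_dense <- grid$n_bins * 5L
    mz <- grid$mass_min + (seq_len(n_dense) - 0.5) * dw
    y <- numeric(n_dense)
    np <- length(template$peak_mz)
    survive <- if (noise$dropout_p > 0) stats::runif(np) >= noise$dropout_p
               else rep(TRUE, np)
    sdlog <- sqrt(log(1 + noise$intensity_cv^2))
    for (j in seq_len(np)) {
      if (!survive[j]) next
      pos <- template$peak_mz[j] +
        if (noise$shift_sd > 0) stats::rnorm(1, 0, noise$shift_sd) else 0
      amp <- template$peak_amp[j] *
        if (sdlog > 0) exp(stats::rnorm(1, -sdlog^2 / 2, sdlog)) else 1
      sg <- template$peak_width[j]
      lo <- max(1L, ceiling((pos - 5 * sg - grid$mass_min) / dw))
      hi <- min(n_dense, floor((pos + 5 * sg - grid$mass_min) / dw) + 1L)
      if (lo > hi) next
      w <- lo:hi
      y[w] <- y[w] + amp * exp(-(mz[w] - pos)^2 / (2 * sg^2))
    }
    if (noise$baseline_amp > 0)
      y <- y + noise$baseline_amp * exp(-noise$baseline_decay * (mz - grid$mass_min))
    if (noise$noise_sd > 0)
      y <- y + stats::rnorm(n_dense, 0, noise$noise_sd)
    raw_spectrum(mz, pmax(y, 0), id = id)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a binned, labelled synthetic dataset
#'
#' Builds templates if the spec does not carry any, then synthesises and bins
#' `sum(n_per_class)` spectra. Each spectrum uses its own counter-based RNG
#' substream derived from the task seed, so results do not depend on
#' generation order. The generating [task_spec()] is attached as attribute
#' `"task_spec"`.
#'
#' @param spec A [task_spec()].
#' @return An unscaled [spectra_dataset()].
#' @export
generate_task <- function(spec) {
  templates <- spec$templates
  if (is.null(templates))
    templates <- make_templates(length(spec$n_per_class), spec$n_peaks,
                                spec$shared_fraction, spec$grid, spec$seed,
                                peak_width = spec$peak_width,
                                amp_range = spec$amp_range %||% c(0.05, 1),
                                class_amp_sd = spec$class_amp_sd %||% 0.5,
                                specific_amp_range = spec$specific_amp_range %||%
                                  spec$amp_range %||% c(0.05, 1))
  n_total <- sum(spec$n_per_class)
  mat <- matrix(0, n_total, spec$grid$n_bins)
  labels <- integer(n_total)
  k <- 0L
  for (cl in seq_along(templates)) {
    for (i in seq_len(spec$n_per_class[cl])) {
      k <- k + 1L
      raw <- synthesize_spectrum(templates[[cl]], spec$noise, spec$grid,
                                 seed = .substream_seed(spec$seed, k),
                                 id = sprintf("c%d_%d", cl, i))
      mat[k, ] <- bin_spectrum(raw, spec$grid, aggregate = "sum")
      labels[k] <- cl
    }
  }
  ds <- spectra_dataset(mat, labels,
                        class_names = vapply(templates, `[[`, "", "class_name"),
                        grid = spec$grid)
  attr(ds, "task_spec") <- spec
  attr(ds, "templates") <- templates
  ds
}

#' Generate a multi-task family for transfer and cumulative learning
#'
#' Produces one large two-class "source" dataset and several smaller "target"
#' datasets on the same bin grid dimensionality. Every target shares
#' `overlap` of its peak positions with the source (as its housekeeping
#' peaks); with `link_targets = TRUE` (default) the class-specific positions
#' of the second and later targets are drawn from the specific-position pool
#' of the first target, emulating a chain of tasks acquired in one domain
#' while the source comes from a different instrument.
#'
#' @param source_spec A [task_spec()] for the source task (templates built
#'   internally if absent).
#' @param target_specs List of [task_spec()]s for the target tasks.
#' @param overlap Fraction of each target's peaks drawn from source positions.
#' @param link_targets Link later targets' specific peaks to the first
#'   target's pool.
#' @return List with elements `source` (a [spectra_dataset()]) and `targets`
#'   (list of datasets, in the order of `target_specs`).
#' @export
generate_task_family <- function(source_spec, target_specs, overlap = 0.4,
                                 link_targets = TRUE) {
  grids <- c(list(source_spec$grid), lapply(target_specs, `[[`, "grid"))
  nb <- vapply(grids, `[[`, 0L, "n_bins")
  bw <- vapply(grids, `[[`, 0, "bin_width")
  if (length(unique(nb)) != 1 || length(unique(bw)) != 1)
    stop("all tasks of a family must share bin_width and n_bins")
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")

  if (is.null(source_spec$templates))
    source_spec$templates <- make_templates(
      length(source_spec$n_per_class), source_spec$n_peaks,
      source_spec$shared_fraction, source_spec$grid, source_spec$seed,
      peak_width = source_spec$peak_width,
      amp_range = source_spec$amp_range %||% c(0.05, 1),
      class_amp_sd = source_spec$class_amp_sd %||% 0.5,
      specific_amp_range = source_spec$specific_amp_range %||%
        source_spec$amp_range %||% c(0.05, 1))
  source_positions <- sort(unique(unlist(lapply(source_spec$templates,
                                                `[[`, "peak_mz"))))
  domain_pool <- NULL
  targets <- vector("list", length(target_specs))
  for (t in seq_along(target_specs)) {
    ts <- target_specs[[t]]
    if (is.null(ts$templates)) {
      # within-task housekeeping peaks: `overlap` of the task's peaks reuse
      # source positions, the rest of the shared set is task-specific but
      # common to all of the task's classes
      n_shared <- floor(ts$shared_fraction * ts$n_peaks)
      n_src <- min(floor(overlap * ts$n_peaks), n_shared)
      min_sep <- max(8 * ts$peak_width, 4 * ts$grid$bin_width)
      shared_pool <- if (n_shared > 0) with_seed(ts$seed + 7L, {
        from_src <- if (n_src > 0) sort(sample(source_positions, n_src)) else numeric(0)
        fresh <- if (n_shared > n_src)
          .draw_positions(n_shared - n_src, ts$grid, min_sep,
                          exclude = source_positions)
        else numeric(0)
        c(from_src, fresh)
      }) else NULL
      pool <- if (link_targets && t > 1) domain_pool else NULL
      ts$templates <- make_templates(
        length(ts$n_per_class), ts$n_peaks,
        shared_fraction = if (ts$n_peaks > 0) n_shared / ts$n_peaks else 0,
        grid = ts$grid, seed = ts$seed, peak_width = ts$peak_width,
        amp_range = ts$amp_range %||% c(0.05, 1),
        class_amp_sd = ts$class_amp_sd %||% 0.5,
        specific_amp_range = ts$specific_amp_range %||%
          ts$amp_range %||% c(0.05, 1),
        shared_pool = shared_pool, position_pool = pool,
        exclude = source_positions)
      if (t == 1) {
        common <- Reduce(intersect, lapply(ts$templates, `[[`, "peak_mz"))
        all_pos <- unique(unlist(lapply(ts$templates, `[[`, "peak_mz")))
        domain_pool <- sort(setdiff(all_pos, c(common, source_positions)))
      }
    }
    targets[[t]] <- generate_task(ts)
  }
  list(source = generate_task(source_spec), targets = targets)
}

#' Default synthetic task family
#'
#' The canonical study conditions of this package: a large broad-peak binary
#' source task (a high-throughput imaging-style acquisition) and three
#' narrower-peak target tasks from a second acquisition domain — a 12-class
#' small task, a 5-class small task and a 2-class medium task — all on one
#' 100-300 Da, 0.1 Da grid (2000 bins). Sizes can be scaled for quick runs.
#'
#' @param seed Integer seed for the whole family.
#' @param n_source_per_class Spectra per source class (default 5000).
#' @param n_12class Spectra per class of the 12-class target (default 20).
#' @param n_5class Spectra per class of the 5-class target (default 24).
#' @param n_2class Spectra per class of the 2-class target (default 1300).
#' @param overlap Fraction of target peaks shared with the source.
#' @return As [generate_task_family()], targets ordered (12-class, 5-class,
#'   2-class).
#' @export
default_task_family <- function(seed = 1L, n_source_per_class = 5000L,
                                n_12class = 20L, n_5class = 24L,
                                n_2class = 1300L, overlap = 0.4) {
  grid <- bin_grid(100, 300, 0.1)
  source_noise <- noise_model(shift_sd = 0.5, intensity_cv = 0.5,
                              baseline_amp = 0.7, baseline_decay = 0.008,
                              noise_sd = 0.04, dropout_p = 0.10)
  target_noise <- noise_model(shift_sd = 0.4, intensity_cv = 0.6,
                              baseline_amp = 0.5, baseline_decay = 0.008,
                              noise_sd = 0.05, dropout_p = 0.10)
  # Class identity rides mostly on weak class-specific peaks close to the
  # noise floor, so classification hinges on the quality of the learned
  # peak-detection filters: a representation trained on the large source
  # transfers, while 12x20 spectra are too few to learn clean filters from
  # scratch. The source "instrument" has broader peaks than the target
  # domain, so fine-tuning on target-domain data has a real resolution gap
  # to bridge. The 12-class task and the 2-class intermediate are hard
  # (tumour-heterogeneity-like); the 5-class task is well separated
  # (species-level differences), like real microbial fingerprints.
  src <- task_spec(grid, n_per_class = rep(n_source_per_class, 2),
                   noise = source_noise, shared_fraction = 0.5, n_peaks = 30,
                   peak_width = 0.18, amp_range = c(0.1, 1),
                   class_amp_sd = 0.1, specific_amp_range = c(0.04, 0.25),
                   seed = seed)
  tg12 <- task_spec(grid, n_per_class = rep(n_12class, 12),
                    noise = target_noise, shared_fraction = 0.68, n_peaks = 25,
                    peak_width = 0.13, class_amp_sd = 0.15,
                    specific_amp_range = c(0.05, 0.12), seed = seed + 1L)
  tg5 <- task_spec(grid, n_per_class = rep(n_5class, 5),
                   noise = target_noise, shared_fraction = 0.6, n_peaks = 25,
                   peak_width = 0.13, class_amp_sd = 0.6,
                   specific_amp_range = c(0.2, 0.7), seed = seed + 2L)
  tg2 <- task_spec(grid, n_per_class = rep(n_2class, 2),
                   noise = target_noise, shared_fraction = 0.68, n_peaks = 25,
                   peak_width = 0.13, class_amp_sd = 0.15,
                   specific_amp_range = c(0.07, 0.2), seed = seed + 3L)
  generate_task_family(src, list(tg12, tg5, tg2), overlap = overlap)
}
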