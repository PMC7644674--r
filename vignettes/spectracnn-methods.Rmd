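---
title: "Classifying 1D mass spectra with small training sets: methods and design"
author: "spectracnn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying 1D mass spectra with small training sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical mass-spectrometry classification — is this biopsy healthy or
tumour, which pathogen is in this culture — must often be solved with a few
dozen labelled spectra per class. Conventional pipelines (SVM, random
forest, LDA) need a preprocessing chain (baseline subtraction,
normalisation, alignment, peak picking) whose parameters are
instrument-specific and whose mis-specification silently destroys the
signal. One-dimensional convolutional networks can classify *raw* binned
spectra, because convolution-plus-pooling learns peak-shape detectors that
are locally translation invariant — precisely the invariance that peak
jitter demands. Their weakness is the small-sample regime, which is where
transfer and cumulative learning come in: learn the representation
(convolutional) portion on a large source dataset, then re-train only the
decision (fully connected) portion on the small target — optionally passing
through intermediate tasks that progressively adapt the representation to
the target domain.

`spectracnn` implements this entire methodology: binning and scaling of
profile spectra, three 1D-CNN reference architectures, training with
class-weighted cross-entropy and checkpoint-on-validation-improvement,
transfer learning by freezing the convolutional stack, cumulative learning
(Scenarios A and B) over a sequence of tasks, the conventional
preprocessing+ML comparison track, and a synthetic-spectrum generator so
every experiment is reproducible offline.

## Data model

A spectrum enters as ordered `(m/z, intensity)` pairs (`raw_spectrum`),
is projected onto a fixed half-open bin grid (`bin_grid`, `bin_spectrum`;
the default aggregate `sum` conserves total ion count), and datasets of
binned spectra travel as a `spectra_dataset`: an `n x n_bins` matrix,
1-based integer class labels, and the grid, so feature index and m/z stay
mutually recoverable. A point exactly on `mass_max` is dropped; a point on
an interior bin edge belongs to the upper bin. Before any model sees the
data each spectrum is scaled linearly to [0, 1] with its own minimum and
maximum (`scale_unit_interval`). Per-spectrum rather than per-dataset
scaling is the default because absolute intensities of profile spectra vary
by orders of magnitude between acquisitions and carry no class information;
a dataset-global option exists. A constant spectrum maps to zeros.

Splits are stratified 60/20/20 train/validation/test
(`stratified_split`): per class, a seeded shuffle followed by
largest-remainder apportionment, which keeps every subset within one sample
of the exact per-class quota — the smallest class keeps its proportion, and
repeated experiment iterations redraw the split with a fresh seed. The
experiment harness (`run_experiment`, `compare_protocols`) re-samples
splits per iteration and reports mean accuracy with its standard deviation
over iterations, with Welch's unequal-variance t-test
(`compare_ttest`) for pairwise protocol comparisons.

## Architectures

`build_architecture` constructs three 1D adaptations of classical image
networks, distinguished by their number of weight-bearing layers:

* `variant_lecun` (4): conv(16, k=21) – pool(4) – conv(32, k=11) – pool(4)
  – dense(128) – output;
* `variant_lenet` (5): one more conv(64, k=11)+pool(4) block and a
  dense(256) head;
* `variant_vgg9` (9): three blocks of two conv(32/64/128, k=9) + pool(4),
  then dense(512) – dense(256) – output.

All convolutions are "valid" (no zero padding: binned spectra start and end
at zero, so nothing informative is lost at the borders), activations are
Leaky ReLU (slope 0.01), dense layers carry dropout 0.5, and the output is
a single sigmoid unit for binary tasks or a softmax otherwise. Kernels are
longer than their image ancestors' because spectral peaks span tens of
bins at 0.1 Da resolution. Filter counts, kernel lengths and dense sizes
are package defaults chosen once and exposed as arguments; parameter
shapes, and therefore the published feature dimensionalities (1,500,
7,084, 15,000 and 19,000 bins), are all supported. Weights are initialised
He-normal (variance `2/fan_in`, matched to rectifiers), biases at zero.

The layer list is explicitly partitioned at `representation_end` (the last
pooling layer): everything before it is the *representation* the transfer
protocols manipulate; flatten onward is the *decision* portion that
`replace_decision_head` rebuilds per task.

## Training

`train` minimises class-weighted cross-entropy
(`weight_c = n_total / (n_classes * n_c)`, so a balanced dataset gets unit
weights) with Adam. The engine is written in R with the batched
convolution/pooling kernels in C++ (RcppArmadillo); their inner GEMMs run
in single precision — the customary precision for CNN training — while all
parameters stay double-precision on the R side. Gradients were verified
against central finite differences to float precision on every layer type.
Parameters are checkpointed only on strict validation-accuracy
improvement and the best checkpoint is returned; training stops early
after `patience` epochs without improvement. Defaults
(`train_config()`): Adam 1e-4, batch 32, at most 100 epochs, patience 10.
The protocol experiments below pass explicit configs documented with each
experiment.

Layers flagged non-trainable are never touched by the optimiser — the
frozen-layer contract is bitwise and is tested for every architecture and
mode. As an optimisation, activations below the first trainable layer are
computed once per training run and cached, which makes decision-head
retraining over a frozen representation cheap; this is mathematically
identical to the full pass because dropout only exists above that boundary.

## Protocols

`run_protocol` executes a list of `protocol_step`s, threading the
representation: the first step trains a fresh model (`train_all`); each
later step replaces the decision head for its task and applies its
representation mode (`fine_tune` = everything trainable from the incoming
state; `freeze_all_conv` = only the decision portion trains;
`freeze_all_conv_but_last` = additionally the last convolutional layer
trains). `protocol_preset` names the four canonical protocols: SCRATCH,
TRANSFER, SCENARIO_A (source → fine-tune on an intermediate task → frozen
representation on the target) and SCENARIO_B (two intermediate fine-tunes,
then freezing all conv layers barring the last for the target).

In cumulative (Scenario B) runs the package uses decaying learning rates
across steps — 1e-3 for the source, 5e-4 for the first fine-tune, 1e-4
afterwards. This is the standard practice for sequential fine-tuning: late
steps take smaller steps so that knowledge accumulated earlier is not
overwritten, and it is what makes the retention property below hold.
`evaluate_retention` quantifies that property: after the full run, each
earlier step's saved decision head is re-attached to the *final*
representation and re-evaluated on that step's held-out test subset.

Open design points resolved here: the published description mixes 60/20/20
splits with 5-fold CV language — implemented as per-iteration stratified
60/20/20 resamples, a rotating-fold-equivalent scheme; whether repeated
iterations re-train the source model is configurable
(`reuse_source = "protocol" | "iteration" | "all"`) because the source
step is identical wherever it appears — sharing it changes only run time.

## The synthetic task family

`default_task_family` generates the package's canonical study conditions:
one large broad-peak binary *source* task and three narrower-peak *target*
tasks (12-class, 5-class, 2-class) on a common 100–300 Da, 0.1 Da grid
(2,000 bins). Each class is a template of Gaussian peaks; per-spectrum
variability layers position jitter, mean-preserving log-normal intensity
fluctuation, an exponentially decaying baseline, zero-clipped additive
noise and random peak dropout (`noise_model`). Spectra are synthesised on
a dense axis at one fifth of the bin width so sub-bin jitter produces
realistic bin-level misalignment, and each spectrum consumes its own
counter-derived RNG substream, so generation order cannot change results.

The family's design choices encode the difficulty regime of real clinical
data rather than a convenient separable toy:

* class identity rides mostly on *weak* class-specific peaks near the noise
  floor (specific amplitudes 0.05–0.12 on the hard tasks, against additive
  noise sd 0.05 plus a 0.5-amplitude baseline), with shared "housekeeping"
  peaks differing across classes only by moderate log-normal intensity
  ratios. Classification therefore hinges on the quality of learned
  peak-detection filters — learnable from a thousand source spectra, not
  from 12 x 20;
* the source "instrument" produces broader peaks (sigma 0.18 Da) than the
  target domain (0.13 Da), so there is a genuine resolution gap that an
  intermediate fine-tune on target-domain data can bridge — the mechanism
  behind cumulative learning's advantage over one-shot transfer;
* the binary intermediate task is *resolving-hard*: weak peaks
  (0.07–0.2) but 600+ spectra per class, so fine-tuning has sustained
  gradients yet the task ends near 0.99 with real margins — which the
  retention experiment needs, because a task stuck at 0.94 keeps several
  percent of its test set within flip distance of the decision boundary
  and no representation could retain it to within 0.02;
* the 5-class task is well separated (species-level fingerprints,
  amplitudes 0.2–0.7), mirroring microbial identification, where transfer
  reaches near-perfect accuracy;
* class imbalance is first-class (`n_per_class` is a vector), exercising
  the weighted loss.

What the generator does *not* emulate: isotope envelopes, charge states,
chemical-noise libraries, within-class biological substructure (each class
is one template; real tumours are heterogeneous mixtures), or
instrument-specific artefacts. Passing the protocol experiments on this
family therefore demonstrates the *mechanisms* — representation transfer,
domain adaptation by fine-tuning, retention under frozen-but-last
cumulative training — not clinical-grade accuracy on any real instrument.

## The experiments the package ships

The acceptance experiments (reproduced by `scripts/acceptance.R` and the
test suite) run at a deliberately reduced scale chosen to finish on a
single CPU core in minutes: source 2 x 1000 spectra, 12-class target
20/class, intermediate 2 x 600, 5-class 100/class, 2,000 bins,
`variant_lenet`, 10 iterations. Configs: source 10 epochs at 1e-3;
intermediate fine-tune 12 epochs at 1e-3 (Scenario A) or the decaying
schedule above (Scenario B); target steps 70 epochs, batch 16, patience 18.
Under these conditions the mean 12-class accuracies order as
SCENARIO_A > TRANSFER > SCRATCH with a Scenario-A-over-scratch gap well
above 0.05 — the qualitative shape of the transfer/cumulative comparison
— and the Scenario B retention losses stay within 0.02 on every earlier
task. Absolute accuracies are far below the published clinical ones (the
12-class task here is *designed* to be at the edge of learnability from
144 training spectra); the ordering and the gaps, not the absolute values,
are the reproducible claims.

## The conventional track

The baseline pipeline (`preprocess_pipeline`) applies, in order:
log-intensity transform (`log(1 + x)`, anchored at zero), SNIP baseline
subtraction (expanding-window min-clipping in the LLS-compressed domain;
the estimate never exceeds the signal), TIC normalisation (unit-sum),
per-class alignment, and MAD-thresholded peak detection (a bin is an apex
iff it is the strict maximum of its ±`halfwindow` neighbourhood and
exceeds `mad_k` times `1.4826 * median |x - median|`). Alignment fits, per
spectrum, the cubic warp `w(x) = a0 + a1 x + a2 x^2 + a3 x^3` by weighted
least squares to greedily matched reference peaks (reference = the
class-average spectrum's peak list; weights = reference intensities,
heavier peaks trusted more), then re-bins on the warped axis — classes are
never mixed. Defaults: 40 SNIP iterations, `mad_k = 3`, halfwindow 20
bins, match tolerance 0.5 Da, all in `preprocess_config`. The feature
matrix is the aligned, normalised intensity at the union of per-class
reference peak bins — a fixed-width resolution of the "peak picking may
yield different counts per spectrum" problem.

`fit_baseline` then grid-searches SVM (`e1071`), random forest
(`randomForest`) or PCA+LDA (`MASS`) on the validation subset, refits the
winner, and reports test metrics. SVM and RF are preceded by chi-square
feature selection on min-max-scaled intensities using the full
classes x (present, absent) contingency table; LDA by PCA. Because the
baselines consume the same `stratified_split` objects as the CNN track,
comparisons are paired down to byte-identical index sets. (The random
forest implementation exposes no maximum depth; its grid uses `maxnodes`
unlimited/32 instead.)

## Numerical and degenerate-input conventions

* Bin-edge membership uses a 1e-9 relative snap so a value printed as
  100.1 lands in the bin starting at 100.1 despite floating-point
  representation.
* Constant spectra: unit-interval scaling maps to zeros; Pearson
  similarity refuses them; MAD peak detection returns an empty list (zero
  noise estimate but no strict maxima).
* Warp fitting requires 4 distinct observed positions; members with fewer
  matches, and single-spectrum classes, pass through alignment unchanged
  with a warning; a fitted warp that is not strictly increasing over its
  range warns, and applying a non-monotone warp re-sorts the axis.
* The Welch comparison of two exactly constant equal accuracy sequences is
  defined as p = 1 (and 0 if constant but unequal) — the statistic itself
  is undefined there.
* All stochastic components (splits, initialisation, shuffling, dropout,
  generation) are seeded; two runs with the same seeds are bitwise
  identical on the same platform. Synthetic generation uses per-spectrum
  substreams, so parallel or reordered generation cannot change data.

## Known limitations

The engine is CPU-only and single-threaded apart from BLAS; it is sized
for the thousands-of-spectra, thousands-of-bins regime, not for
ImageNet-scale sources. The synthetic generator's noise model is a
stand-in informed by the qualitative literature on MS variability (shifts,
intensity fluctuation, baseline drift, dropout); it is labelled synthetic
throughout and no claim about real-instrument accuracy follows from it.
Real-data ingestion is limited to delimited text (wide or long CSV);
vendor raw formats and mzML are out of scope.
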