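---
title: "Detecting structural anomalies in spatiotemporal Hi-C: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting structural anomalies in spatiotemporal Hi-C: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Time-resolved Hi-C experiments produce, for each chromosome, an ordered
sequence of balanced contact matrices — one per developmental stage, time
point, or treatment condition. Chromatin architecture evolves smoothly
through such series: topologically associating domains (TADs) consolidate
or dissolve gradually, loops strengthen or fade. Abrupt, localized
departures from that smooth trajectory are interesting precisely because
they are rare: structural variants, experimental artifacts such as a
mislabeled time point, or genuine fast remodeling events (for example,
cohesin-dependent loop loss). `hicspot` detects such departures without
labels, by learning what normal spatiotemporal dynamics look like and
flagging what the learned model cannot reproduce.

## The model

The detector is a spatiotemporal autoencoder. An input sequence
$X = \{X_1, \dots, X_T\}$ of normalized $H \times W$ windows is mapped to a
reconstruction $\hat X$ through three blocks:

1. **Spatial encoder.** Each frame passes independently through three
   convolutions (kernels $7,5,3$; strides $2,2,1$; paddings $3,2,1$), each
   followed by batch normalization and ReLU. A $50 \times 50$ window is
   reduced to $13 \times 13$ feature maps.
2. **Temporal encoder–decoder.** A stack of five ConvLSTM layers (kernel 3,
   hidden sizes $64,64,32,64,64$ in the full configuration) consumes the
   frame sequence. Gates are convolutions over the current input and the
   previous hidden state:
   $i_t, f_t, o_t = \sigma(\cdot)$, $\tilde c_t = \tanh(\cdot)$,
   $c_t = f_t \odot c_{t-1} + i_t \odot \tilde c_t$,
   $h_t = o_t \odot \tanh(c_t)$. States start at zero; the top layer's
   hidden sequence, one map per frame, goes to the decoder. The recurrence
   is length-agnostic, so a trained model accepts any $T \ge 1$.
3. **Spatial decoder.** Three transposed convolutions mirror the encoder
   (kernels $3,5,7$; strides $1,2,2$; paddings $1,2,3$), with batch
   normalization and ReLU after the first two and a sigmoid on the last, so
   $\hat X \in (0,1)^{T \times H \times W}$. Output padding is computed at
   build time from the recorded encoder sizes, which recovers the input
   size exactly ($13 \to 13 \to 25 \to 50$ with output paddings $0,0,1$).

Training minimizes the mean squared reconstruction error
$\mathcal L = \frac{1}{THWC}\sum_t \lVert X_t - \hat X_t \rVert_2^2$
with AdamW (learning rate and weight decay $10^{-4}$ at full scale, batch
size 32), early stopping on validation loss (patience 25 within at most 100
epochs), and restoration of the best-validation checkpoint. Anomaly
evidence is the reconstruction discrepancy: per-pixel maps are
$|X - \hat X|$, and the per-frame anomaly score is frame $t$'s mean squared
error, so the mean score over frames equals the training loss — the frame
score is the exact per-frame decomposition of the optimized quantity.

Because no deep-learning framework is available to R in this toolchain,
the network — batched convolution and transposed convolution with their
backward passes, batch normalization, ConvLSTM backpropagation through
time, AdamW, dropout, early stopping — is implemented in the package
itself, with the convolution inner loops in C++ (im2col + BLAS gemm,
optionally in single precision). Analytic gradients are verified against
central finite differences through the entire network in the test suite.

## Interpretation choices in the architecture

Several details are underdetermined by the field's usual description of
this architecture; the package resolves them as follows and exposes each
in `model_config()`:

* **Encoder channel widths** are $(32, 64, 64)$ so the encoder output
  matches the first ConvLSTM hidden size — the minimal consistent choice.
* **One five-layer ConvLSTM stack** processes the whole sequence; we do
  not split it into separate encoder/decoder halves with copied states.
  Layer $l$ consumes the full hidden sequence of layer $l-1$.
* **Batch normalization before activation**, running statistics in
  evaluation mode (required for deterministic inference).
* **Dropout (0.3)** after each encoder/decoder activation and between
  ConvLSTM layers, active only in training mode.
* **ConvLSTM states initialize to zero**; the forget-gate bias
  initializes to 1 (standard practice that stabilizes early training).
* **Gradient-norm clipping** is available (`max_grad_norm`) but disabled
  by default.

## Input preparation

Contact maps are assumed balanced; `NaN` entries from balancing become 0
(unmappable bins carry no interaction evidence). Windows of $50 \times 50$
bins are taken along the diagonal with a configurable stride, optionally
sweeping rightward off the diagonal until a maximum genomic span (2 Mb by
default) is covered; our reading restarts the rightward sweep at every
diagonal anchor. Windows that would overrun the chromosome end are dropped
rather than padded, so the learned distance decay is never distorted by
artificial zeros. Values are clipped to fixed bounds and rescaled by those
bounds — *not* by per-window extrema, which would make scores incomparable
across windows. Presets follow common practice: counts at 40 kb clip to
$[0, 100]$; balanced 10 kb maps clip to $[0, 0.02]$. Chromosome-level
train/validation/test splits (conventionally: chr19 validation, chr2 and
chr6 test, the rest training) prevent leakage between overlapping windows.

## The perturbation simulator

Synthetic series provide ground truth that real data cannot. Contact decay
follows the power law $k\,(d + p)^{c}$ with distance $d$ in bins and offset
$p \ge 1$ guarding $d = 0$. Standard experimental values: TAD baseline
$k_t = 400$, exponent $c_t = -0.8$; weak-region baseline $k_{weak} = 200$
(same exponent); noise baseline and exponent $(50, -0.7)$, fired per entry
with probability $0.5$ and added or subtracted with equal probability.
Perturbations act on the strict lower triangle ($x > y$) and are mirrored,
so the main diagonal is untouched:

* **TAD add** raises entries toward the $k_t$ profile plus signed noise,
  replacing only when larger (a de novo TAD never decreases contacts).
* **TAD split** lowers entries toward the $k_{weak}$ profile with the noise
  always subtracted, replacing only when smaller; negative intermediate
  values floor at 0.
* **TAD shift** copies the block, weakens the vacated region via the split
  procedure, and superimposes the copy at the destination with the same
  replace-if-larger rule as the add — keeping shift = split(vacate) then
  add(copy).
* **TAD strength** rescales the target profile by a factor (0.5 or 1.5
  conventionally); updates go only in the intended direction.
* **Loop strength up** writes the element-wise mean of the top five
  reference loop windows where it exceeds the current value, capped (by
  default at the active clip bound) for numerical stability.
* **Loop strength down** expands the loop window by two bins and replaces
  each entry by the mean of the four flanking windows, absorbing the peak
  into the local background.

Concurrent perturbations in a frame must keep a 10-bin separation
(boundary tolerance); violations are an error naming the colliding
regions. A signed-noise draw consumes one uniform per entry plus one per
firing entry (column-major over the strict lower triangle), so every
operation is reproducible from a seed.

### The baseline generator

Real baseline series are emulated by
`generate_baseline_series()`: a background power law ($k_{bg} = 100$,
$c_{bg} = -1$), TAD blocks at the $k_t$ profile, Gaussian loop foci
(amplitude 1.5 times the local TAD signal, width 1.5 bins) at TAD boundary
contacts, and multiplicative lognormal pixel noise ($\sigma = 0.1$, mean
1). TAD and loop intensities grow by 10% per frame (`temporal_drift`),
emulating the smooth consolidation of domains seen across developmental
time courses, with independent per-frame noise. These defaults are the
package's chosen study conditions for all synthetic experiments; they are
deliberately simple. The generator reproduces the statistical features the
detector relies on — symmetry, non-negativity, power-law decay, nested
domains, focal loops, smooth temporal evolution — but not read-depth
variation, balancing artifacts, compartment checkerboards, or
distance-dependent noise heteroscedasticity of real Hi-C. Passing
synthetic benchmarks therefore demonstrates the mechanics of detection,
not performance on any particular real dataset.

## Desk-scale evaluation protocol

The package's synthetic benchmarks are sized for a single CPU:

* **Reconstruction fidelity.** A 6-frame, 947-bin series gives exactly 300
  diagonal windows at stride 3, split 240/30/30 into
  train/validation/held-out. A reduced model (encoder channels
  $(16,32,32)$, ConvLSTM hidden $(32,32,16,32,32)$) trains for at most 30
  epochs with early-stopping patience 5 at learning rate $2 \times 10^{-3}$
  — the full-scale $10^{-4}$ rate is tied to 100-epoch GPU-scale runs and
  underfits severely inside a 30-epoch budget. Held-out per-frame Pearson
  and Spearman correlations between input and reconstruction are averaged
  over frames and windows. One fully trained model per seeded run: the
  Spearman correlation in particular keeps improving late in training (the
  ranks of the many small far-from-diagonal values are learned last), so a
  single 30-epoch run is preferred over several undertrained ones.
* **Time-swap.** Two frames of a 6-frame, 400-bin series are interchanged;
  per-frame anomaly scores are aggregated over all diagonal windows, and
  the swapped frames should rank highest.
* **Scenario detection.** The four-perturbation scenario (de novo TAD at
  T2, strength increase at T4, shift at T5, split at T6) is applied to a
  clean series; a frame is flagged when its score exceeds
  $\mathrm{mean} + k\,\mathrm{sd}$ ($k = 1$) of the *matched clean-series*
  scores — detection is elevation relative to normal dynamics, which the
  simulation harness can supply exactly. The same trained model serves all
  seeded data realizations; the null scenario (no perturbation) controls
  the false-flag rate.

## Numerical choices and degenerate inputs

* Frame scores use squared error (the loss decomposition); pixel maps use
  absolute error (interpretable as contact-probability discrepancy).
* The metrics panel reports per frame: MSE, L1, structural similarity
  (Gaussian-windowed, $11 \times 11$, $\sigma = 1.5$, data range 1,
  shrinking to the largest odd window on small frames), Pearson and
  Spearman correlations, PSNR ($10\log_{10}(1/\mathrm{MSE})$, capped at
  100 dB so identical frames stay finite), range-normalized RMSE, KL and
  JS divergences (flatten, add $\varepsilon = 10^{-10}$, normalize to sum
  1, natural log), and cosine similarity. Correlations of constant frames
  are reported `NA` and excluded from averages.
* Matrix symmetry tolerance is $10^{-8}$; stored triangles are mirrored on
  load; asymmetric full matrices are rejected rather than silently
  averaged.
* Training fails loudly on non-finite loss, with the epoch index.

## Known limitations

* Only intra-chromosomal, fixed-resolution series; no `.hic`/`.cool`
  (HDF5) reader is bundled — matrices are exchanged through a dense
  tab-separated dialect (`cooler dump` produces compatible content).
* The simulator perturbs TADs and loops, not compartments or
  translocations, and emits balanced-signal matrices, not read-level data.
* An autoencoder whose latent grid is not pixel-compressive can, with
  enough training, copy its input — including anomalies. The desk-scale
  protocols deliberately train briefly; production use should monitor
  validation loss and prefer the earliest adequate checkpoint.
* Anomaly scores are relative, not calibrated probabilities; the
  $k$-threshold is a screening rule, and biological interpretation needs
  orthogonal evidence.
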