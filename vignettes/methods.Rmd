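---
title: "Contrastive signal-label sleep staging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive signal-label sleep staging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Sleep staging assigns each 30-second epoch of an overnight recording to
one of the five AASM stages W, N1, N2, N3, REM. `sleepcontrast`
implements a dual-encoder contrastive formulation of this task for
single-channel EEG, in the style of contrastive language-image
pre-training: a convolutional **signal encoder** maps an epoch $x$
(3000 samples at 100 Hz) to a unit vector $S \in \mathbb{R}^{d_e}$, a
small transformer **label encoder** maps a categorical stage $y$ to a
unit vector $L \in \mathbb{R}^{d_e}$, and training aligns matched
$(S_i, L_i)$ pairs while pushing mismatched pairs apart.

For a batch of $n$ pairs the model forms the temperature-scaled cosine
similarity matrix $M_{ij} = \tau \cos\langle S_i, L_j\rangle$. Because
both embeddings are L2-normalized, the cosine reduces to a dot
product. The objective is the symmetric cross-entropy (InfoNCE): the
mean of a row-wise softmax cross-entropy with target $i$ (signal
$\rightarrow$ label) and the same over columns (label $\rightarrow$
signal),

$$\mathcal{L} = \tfrac12\Big(
  \tfrac1n\sum_i -\log \tfrac{e^{M_{ii}}}{\sum_j e^{M_{ij}}} +
  \tfrac1n\sum_j -\log \tfrac{e^{M_{jj}}}{\sum_i e^{M_{ij}}}\Big).$$

At inference each stage's embedding is cached as a **prototype**; an
epoch is assigned the stage whose prototype has the highest cosine
similarity to its embedding, with ties (within numerical noise, 1e-9)
broken toward the lowest stage code W < N1 < N2 < N3 < REM.

Because the label set has only five elements, an unconstrained random
batch would contain duplicate labels, turning off-diagonal cells into
false negatives. The training loop therefore draws **stratified
batches**: one random epoch per distinct stage, so every off-diagonal
cell is a true negative and the batch size is at most five.

## The signal encoder

Two parallel 1-D convolution branches tuned to different time scales:

* **small branch**: Conv1D(64 filters, kernel 64, stride 8), whose
  window spans 0.64 s at 100 Hz and resolves alpha-range and faster
  rhythms;
* **large branch**: Conv1D(64 filters, kernel 512, stride 64),
  spanning 5.12 s, long enough to contain whole delta waves.

Each branch applies leaky-ReLU, then a channel/spatial attention block
(CBAM): channel attention pools the feature map over positions
(average and max), passes both descriptors through a shared
squeeze-excite MLP (reduction ratio 8, ReLU between squeeze and
expand) and gates channels with a sigmoid; spatial attention pools
over channels, applies a width-7 same-padded convolution over the two
pooled profiles and gates positions. Both gates are strictly in
(0, 1) and preserve the feature-map shape. After CBAM each branch max
pools, applies two further same-padded Conv1D(64, kernel 8, stride 1)
layers and pools again; the flattened branch outputs are concatenated
and linearly projected to $d_e$, then L2-normalized.

Design notes on points the architecture description leaves open:

* The published dimension annotations assign both attention maps the
  same shape, which cannot hold simultaneously for channel and spatial
  gating; standard CBAM semantics are used (channel attention pools
  over positions, spatial attention over channels).
* The exact layer stack after CBAM is not fully enumerated in the
  source architecture; two post-CBAM convolutions per branch are used,
  and every count lives in `encoder_config()` so alternatives are one
  configuration away.
* Pooling is 8/8 on the small branch and 4/4 on the large branch: the
  large branch's 39-position map cannot sustain two 8/8 pools.
* The channel-attention MLP includes a ReLU between squeeze and
  expand, the standard CBAM form.

## The label encoder

A stage code indexes a learned 5-row embedding table; the row is
linearly projected ($W_{tran}$) to the hidden width $h$, prepended
with a learnable class token $c$, and passed through $K$ pre-norm
residual blocks:

$$\tilde\psi = \mathrm{MHA}(\mathrm{Norm}(\psi)) + \psi,\qquad
  \psi' = \mathrm{MLP}(\mathrm{Norm}(\tilde\psi)) + \tilde\psi,$$

with multi-head attention, layer normalization, and a two-layer ReLU
MLP with dropout between its layers (training only; inference is
deterministic). The final state of the class token, projected to
$d_e$ and normalized, is $L$. With the attention output projection and
the MLP second layer zeroed, the residual path reproduces the input
exactly -- a property the tests assert, and a useful sanity check on
the pre-norm wiring.

How to vectorize a categorical label is genuinely open (one-hot, text,
or sequence representations are all conceivable); the 5-entry learned
embedding table with sequence length 1 is the minimal choice and is
declared as this package's reading, not as the original authors'.

## Preprocessing

* **Baseline correction.** The slow drift that electrode movement and
  physiology impose on EEG is estimated as the running median over a
  1-second centered window (edges by reflection) and subtracted.
  Subtraction -- rather than replacing samples by the median -- keeps
  the waveform the encoder needs while removing the drift term; a
  1 s window passes rhythms at and above about 0.5 Hz largely into
  the signal term. The window rounds to the nearest odd sample count
  (1.0 s at 100 Hz becomes 101 samples).
* **Epoching.** Epoch $i$ covers samples $[3000i, 3000(i+1))$; a
  trailing partial epoch is truncated with a warning.
* **Label expansion.** Hypnogram annotations (EDF+ track or 2-column
  CSV) are expanded to per-epoch labels; stages 3 and 4 merge into N3
  per the AASM standard; movement/unscored epochs become DROP and are
  removed; gaps or unknown tokens are errors, never guesses.
* **Peripheral wake trimming.** Everything before the first and after
  the last non-wake epoch is discarded except a 60-epoch (30 min)
  flanking margin, the common convention for overnight recordings
  whose lights-on periods dwarf the night.
* **Per-epoch z-scoring** (zero mean, unit variance) removes
  between-subject and between-device amplitude scale. It is an
  addition beyond the published preprocessing, toggleable via
  `normalize_epochs`.

## The synthetic generator

`generate_recording()` emulates exactly the statistical structure the
encoder and the preprocessing act on -- stage-dependent band content
plus slow drift -- and nothing more. Per stage: W is alpha-dominant
(8-13 Hz), N1 theta-dominant (4-8 Hz), N2 sigma-dominant (12-14 Hz
with additional 0.5-1 s Hann-windowed spindle packets), N3
delta-dominant (0.5-4 Hz) at high amplitude, REM a low-amplitude 2-3
Hz sawtooth with moderate theta. Band components are sums of
random-phase sinusoids plus Gaussian broadband noise; drift is a
0.02 Hz sinusoid plus a linear ramp (default 50 uV) so that the
median-filter stage has something to remove. Dominant bands are
pairwise distinct, and a naive band-power nearest-centroid classifier
separates the stages with > 95% accuracy -- which means a failed
end-to-end training test implicates the model code, not the data.

What the generator does **not** emulate: artifacts, stage transitions
within an epoch, inter-subject variability, realistic 1/f spectra, or
any waveform morphology beyond the sawtooth and spindle sketches.
Passing the end-to-end test therefore demonstrates that the
architecture, gradients and training loop work as specified -- not
that the model reaches any particular accuracy on real recordings.

## Numerical and optimization choices

* All forward/backward passes are hand-written matrix code; gradients
  of every layer are verified against central finite differences in
  the test suite (tolerance 1e-4, typically agreeing to ~1e-9).
* Adam (lr 1e-3, default betas) over the full parameter tree;
  optimizer and learning rate are configurable.
* Temperature $\tau$ is learnable through its logarithm (positivity by
  construction), initialized at 14.3 ($\approx 1/0.07$, the standard
  contrastive-pretraining convention); `fixed_temperature = TRUE`
  recovers the raw cosine scale.
* Initialization: He normal for the convolution stacks (they feed
  leaky-ReLU), unit-variance normal for the label embedding table (the
  standard embedding convention; it also separates the five label
  tokens from step 0, avoiding a slow escape from the uniform-softmax
  plateau at $\log 5$), fan-in uniform elsewhere; layer-norm gains
  start at 1.
* Determinism: model construction and training consume only the seeds
  in their configurations; two runs with identical seeds produce
  byte-identical loss traces and predictions.
* Resampling to the mandatory 100 Hz uses a hand-written polyphase
  resampler (zero-stuffing, windowed-sinc FIR low-pass designed with
  `signal::fir1`, decimation, reflection padding, group-delay
  compensation), preserving sub-Nyquist band power to ~0.1%.
* EDF writing digitizes to 16 bits over a symmetric physical range,
  so round trips are exact to half a quantization step.

## Problem sizes used in tests

The test suite trains the reduced-width configuration ($d_e = 32$,
$K = 2$, 300 stratified steps) on 80 epochs per stage (100 generated,
80/20 split) -- small enough to run comfortably on one CPU while large
enough that the contrastive objective must genuinely learn all five
stages. With these conditions the held-out balanced accuracy across
representative seeds ranges from high-0.8 to 1.0; the fixed-seed run
asserted in the tests reaches 0.98. `scripts/acceptance.R` re-runs the
same pipeline end to end under a caller-supplied seed.

## Known limitations

* Trained weights from this package are not transferable to real
  polysomnography without retraining; the generator's simplifications
  guarantee that.
* Single-channel EEG only; no EOG/EMG branches.
* Batching is capped at five (one epoch per stage). A multi-positive
  masked variant for larger batches is a natural extension and
  deliberately out of scope.
* The pure-R implementation favors verifiable correctness over speed;
  a 300-step training run takes on the order of a minute.
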