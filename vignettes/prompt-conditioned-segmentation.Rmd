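---
title: "Prompt-conditioned segmentation: model, losses, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt-conditioned segmentation: model, losses, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promptseg)
```

## The problem

A single segmentation network usually answers a single question: *where is
the tumor?* In clinical workflows the question changes from study to study —
segment the liver, now the spleen, now the left kidney — and training one
network per structure is wasteful and brittle. promptseg implements a
prompt-conditioned alternative: one encoder–decoder network whose target is
selected at inference time by a natural-language instruction such as
`"Segment the Glioma region"` or `"Identify the Right kidney"`. The language
signal enters the network through feature-wise linear modulation (FiLM) and
conditional batch normalization (CBN) of the visual bottleneck, so the same
weights produce different masks for different prompts.

Everything — network layers, backpropagation, AdamW — is implemented in base
R over BLAS matrix products, so the package trains and evaluates entirely
offline on a CPU. That choice also fixes the scale the package is designed
for: desk-scale experiments on synthetic scenes, not GPU-scale benchmarks.

## The model

**Encoder.** Four stages; each stage first halves the spatial extent with
2×2 stride-2 max pooling and then applies a residual double-convolution
block, doubling the channel count: for a `H × W` input the stages produce
`64×H/2×W/2`, `128×H/4×W/4`, `256×H/8×W/8`, and a `512×H/16×W/16`
bottleneck (at the default `base_width = 64`). Pooling *precedes* the
convolution block at every stage — this is the only ordering consistent with
those stage dimensions. Each block is two 3×3 convolution + batch-norm +
LeakyReLU(0.1) layers with a residual shortcut (identity when channel counts
match, a learned 1×1 projection otherwise), followed by two attention
mechanisms and dropout (δ = 0.1):

- **Squeeze-and-excitation (SE)**: global average pooling per channel, a
  two-layer bottleneck with reduction ratio r = 16, sigmoid gates that
  rescale each channel. No bias terms.
- **Spatial attention**: the channel-wise average- and max-pooled maps are
  concatenated and convolved with a single 7×7 filter; the sigmoid of the
  result rescales every pixel. Note this is only the *spatial* branch of
  the CBAM family — no channel branch precedes it; the SE block already
  plays that role here. SE is applied before the spatial branch.

**Text path.** Prompts are built from a synonym table (e.g. glioma →
"Glioma", "Brain tumor", "Neoplasm", …) substituted into instruction
templates, tokenized with `[CLS]`/`[SEP]` markers under a 16-token cap, and
embedded to a fixed 768-dimensional vector by mean pooling the per-token
vectors over non-padding positions. The token embedder is a pluggable
interface. The default is a deterministic hash embedder: each token string
seeds an RNG that emits its fixed 768-vector. This carries no linguistic
structure beyond token identity — two synonyms of the same organ are *not*
close in embedding space — which makes it a conservative choice: the fusion
pathway must learn the synonym groupings itself, and nothing about the
passing tests depends on pretrained semantics. A contextual pretrained
encoder can be dropped in through the same interface; in either case the
embedder is frozen and owns no trainable parameters. Padding positions are
excluded from the mean (the pooled vector should not depend on how much
padding the cap leaves).

**Fusion.** At the bottleneck, two affine maps generate per-channel scale
and shift from the prompt vector: `E_fused = (1 + γ) ⊙ E4 + β` (FiLM; the
`1 +` keeps the zero-initialized maps at the identity). An SE block then
rebalances the fused channels; CBN normalizes with batch statistics but
with γ/β *generated from the prompt*; a residual link adds back the raw
bottleneck (`E_final = E4 + E_CBN`, read literally as the raw `E4`); and the
result is L2-normalized along the channel dimension at every spatial
location, with an ε-guarded denominator. The model's own description places
CBN both at the bottleneck (in its equations) and at the decoder's
128-channel stage (in its prose); both sites are implemented and enabled by
default (`fusion_config(cbn_sites = c("bottleneck", "decoder"))`), each
selectable for ablation. FiLM/CBN generating maps are initialized near zero
(σ = 0.02, CBN scale bias at 1) so training starts from an unconditioned
network and learns the conditioning.

**Decoder.** Three stages of 2×2 stride-2 transposed convolution →
concatenation with the matching skip → residual attention block. The
transposed convolutions preserve their channel count, so the concatenations
are `512+256 = 768`, `256+128 = 384`, `128+64 = 192` wide, and the blocks
reduce to 256/128/64. Because the encoder pools before its first block, the
third decoder stage lands at `H/2 × W/2`; a fourth, skip-free 2×2
transposed convolution restores the full `H × W` before the 1×1 sigmoid
head on 64 channels. This keeps every printed fact — three skip
concatenations, a 64-wide head input, a 1×1 head, output at input
resolution — simultaneously true. Decoder blocks use the same dropout rate
as the encoder's. The default binarization threshold is τ = 0.5.

## Losses

Six objectives, selectable by name or combinable as a weighted sum:

| name | definition | notes |
|---|---|---|
| `dice` | `1 − (2Σp·m + ε)/(Σp² + Σm² + ε)` | squared-denominator soft Dice |
| `focal` | `−mean[(1−p)^γ log p · m + p^γ log(1−p) · (1−m)]`, γ = 2 | no class-balance prefactor |
| `jaccard` | `1 − (Σp·m + ε)/(Σp + Σm − Σp·m + ε)` | soft IoU |
| `tversky` | α = 0.7 on false positives, β = 0.3 on false negatives | α = β = 0.5 recovers the non-squared Dice form |
| `dicebce` | dice + mean binary cross-entropy, unit weights | |
| `hausdorff` | distance-transform-weighted MSE (training surrogate) | see below |

A smoothing ε (default 1e-6, settable to 0 for exact oracle checks) keeps
the ratio losses defined on empty masks. The boundary Hausdorff distance
itself — maximum over both directions of the largest nearest-neighbour
distance between boundary point sets, boundaries being foreground pixels
with a 4-connected background neighbour or on the image border — is exact
but not differentiable in the predicted probabilities, so the *training*
objective under the `hausdorff` name is a documented surrogate: squared
error weighted by `1 +` the distance transforms to the ground-truth and
predicted foregrounds (both treated as constants). It is zero exactly on a
perfect binary match and grows as errors move away from the target
boundary; it is not the boundary metric, which remains the evaluation
quantity.

## Metrics

Ten per-image metrics: IoU, Dice, F1 (≡ Dice for binary masks), pixelwise
average precision ("mAP": area under the precision–recall curve over all
score thresholds, step-interpolated, averaged over classes when several are
evaluated), boundary Hausdorff distance, Cohen's κ on the pixel contingency
table, specificity, recall, precision, pixel accuracy. Per-image metrics
are averaged over the evaluation set.

Conventions worth stating: any count-ratio metric with a zero denominator
returns 1 when its associated error count is also zero (empty ground truth,
empty prediction) and 0 otherwise, consistently across metrics. When
exactly one mask is empty the Hausdorff distance returns the image diagonal
as a documented sentinel. κ is algebraically bounded by 1, and the test
suite asserts the implementation can never exceed it — a bound worth
asserting because published tables occasionally print κ values above 1,
which can only arise from computation errors, never from the definition.

## Synthetic scenes

Real brain-MRI and abdominal datasets are deliberately out of scope; the
generators produce seeded scenes that preserve the *structure* of the two
benchmark regimes:

- **Single-lesion** (`single_lesion_spec()`): one lesion per image on a
  smoothly varying dark background — irregular infiltrative boundaries
  (low-order Fourier perturbation of a circle, glioma-like), smooth
  encapsulated discs (meningioma-like), or small compact ellipses
  (pituitary-like), with class-specific intensity ranges.
- **Multi-organ** (`multi_organ_spec()`): every image contains all four
  organ-like regions — a large lobe (liver), a mid-sized disc (spleen), and
  two small ellipses (kidneys, lateralized to opposite image halves, with
  distinct intensities) — placed disjointly by rejection sampling against
  the exact occupancy of already-placed regions with a 2-pixel gap.

Shapes are star-convex with analytic radius functions, so rasterization is
exact and bit-reproducible per seed. Additive Gaussian noise (σ = 0.05 on
the `[−1, 1]` scale) is the only corruption; there are no bias fields, no
partial-volume effects, no anatomy. Consequently the multi-organ scenes are
*intensity-separable*: each organ class occupies a distinct intensity band,
which real abdominal MRI does not grant. What the passing tests therefore
demonstrate is that the conditioning pathway works — the prompt, not the
image, selects which region is produced (matched prompts recover their
target; swapped prompts must not) — and *not* that the architecture reaches
any particular accuracy on real data. The multi-organ design is the
important one for that claim: since all four organs are present in every
image, the correct mask is unrecoverable from the image alone.

## Training protocol

The reference protocol is AdamW (decoupled weight decay 1e-4), initial
learning rate 1e-4, cosine annealing to 0, 500 epochs, dropout 0.1,
128×128 inputs normalized to `[−1, 1]`, stratified 80/20 split, 10
independent runs per configuration. All of it is configurable
(`train_config()`), and the harness (`multi_run()`) reports per-metric
mean, standard deviation, 95% Student-t intervals and Shapiro–Wilk
normality checks across runs; a constant sample is rejected as degenerate
rather than given a meaningless p-value. Prompts are re-drawn from the
synonym table every epoch ("dynamic" mode) so the model sees every wording
of its target classes; the target class of a sample never changes.

**Desk scale.** The packaged experiments and tests run a quarter-width
model (`base_width = 16`, topology unchanged) on 64×64 scenes with batch
size 8 — sizes chosen so a full conditioning experiment runs in minutes on
one CPU core. Two protocol choices matter and were fixed as design
decisions: the desk-scale learning rate is 2e-3 rather than the reference
1e-4, scaling the rate to the much smaller model and the ~500-step total
budget (with cosine annealing, a 1e-4 rate cannot move a freshly
initialized network measurably in so few steps); and the conditioning
experiment uses 120 generated scenes (96 train / 24 validation), since with
CPU-cheap synthetic data the natural way to control the generalization gap
of a from-scratch model is more scenes rather than more passes over few
scenes. Training is bit-deterministic under a fixed seed: data generation,
initialization, shuffling, dropout and prompt wording all derive from it.

## Numerical choices

- Batch normalization uses biased batch variance both in-batch and for the
  running estimate (momentum 0.1, ε = 1e-5); eval mode uses running
  statistics. Training at batch size 1 is permitted but the batch statistics
  are then degenerate — expect instability.
- Max-pool ties break toward the earliest window position, keeping forward
  passes bit-reproducible.
- The L2 channel normalization adds its ε *under* the square root, so
  all-zero channel vectors map to zero rather than NaN.
- Focal-loss probabilities are clipped to `[1e-7, 1 − 1e-7]` before logs;
  the clipped region has zero gradient.
- A global gradient-norm clip (default 5) guards the small-batch training
  loop against rare early spikes; it is configurable and can be disabled.
- Weight initialization is He-scaled for convolutions; FiLM/CBN generating
  maps start near the identity mapping as described above.

## Known limitations

- The hash embedder makes prompts *discrete keys* rather than semantic
  vectors: generalization to unseen phrasings of a class requires those
  phrasings to be in the synonym table. This is by design for an offline,
  deterministic test bed; plug in a pretrained encoder for semantics.
- CPU training in R is practical only at desk scale; the full 500-epoch,
  batch-512 reference protocol is expressible but not intended to be run
  here.
- Dropout inside decoder blocks, and inference-time dropout deactivation,
  follow standard practice where the source description is silent; both are
  assumptions, stated here rather than hidden.
- The spatial-attention branch follows the single-7×7-filter description
  exactly, which differs from the original CBAM publication (no channel
  branch, no dual-pool MLP).

## Reproducing the numbers

`scripts/acceptance.R --seed <s> --out <path>` re-derives every headline
quantity — architecture widths from an instantiated full-scale model,
loss/metric/Hausdorff oracle deviations, harness statistics, bit-level
training determinism, and the matched- vs swapped-prompt Dice of the
conditioning experiment — and writes them to JSON. The test suite asserts
the same properties with `testthat`.
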