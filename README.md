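# promptseg

Prompt-conditioned binary segmentation of 2D grayscale images in pure R.

One encoder–decoder network answers many segmentation questions: the target
structure is selected at inference time by a natural-language instruction
("Segment the Glioma region", "Identify the Right kidney") rather than by a
fixed output head. The prompt is embedded to a fixed 768-dimensional vector
and injected into the visual bottleneck through **feature-wise linear
modulation** (FiLM) and **conditional batch normalization** (CBN), so a
single set of weights produces different masks for different prompts.

The architecture is an attention-augmented U-Net:

- four encoder stages of (2×2 max-pool → residual double 3×3 convolution
  block), widths 64/128/256/512 for an `H×W` input at the default scale,
  each block carrying squeeze-and-excitation channel attention and a
  7×7-convolution spatial attention branch;
- cross-modal fusion at the bottleneck:
  `E_fused = (1 + γ) ⊙ E4 + β` with `γ = W_γ v_t + b_γ`,
  `β = W_β v_t + b_β`, followed by SE recalibration, CBN whose scale/shift
  are generated from `v_t`, a residual link `E_final = E4 + E_CBN`, and
  channel-wise L2 normalization;
- a decoder of 2×2 stride-2 transposed convolutions with skip
  concatenations (768→256, 384→128, 192→64), a prompt-conditioned
  normalization at the 128-channel stage, and a 1×1 sigmoid head.

Because no deep-learning framework is required, every layer, the manual
backpropagation and the AdamW optimizer are implemented on top of BLAS
matrix products: the package trains desk-scale models on one CPU core,
fully deterministically under a fixed seed.

It ships six training objectives (Dice, focal γ=2, Hausdorff surrogate,
Jaccard, Tversky α=0.7/β=0.3, Dice+BCE), ten evaluation metrics (IoU, Dice,
F1, pixelwise mAP, boundary Hausdorff distance, Cohen's κ, specificity,
recall, precision, pixel accuracy), seeded synthetic scene generators for a
single-lesion and a multi-organ benchmark, a multi-run statistical harness
(mean ± sd, 95% t-intervals, Shapiro–Wilk), and a command-line interface.

## A worked example

Generate multi-organ scenes — every image contains a liver-like lobe, a
spleen-like disc and two kidney-like ellipses, so the image alone cannot
tell the network which mask to produce — then train a quarter-width model
and query it with two different prompts:

```r
library(promptseg)

samples <- generate_multi_organ(48, multi_organ_spec(64), seed = 1)
samples <- attach_prompts(samples, organ_synonym_table(), seed = 2)
samples <- lapply(samples, preprocess, size = 64)
sp <- split_samples(samples, 0.8, seed = 3)

model <- promptseg_model(base_width = 16, seed = 4)
model <- train_model(model, sp$train,
                     train_config(lr = 3e-3, epochs = 30, batch_size = 8,
                                  loss = loss_config("dice"), seed = 5))

ev <- evaluate_model(model, sp$val)
print(ev$mean)

img <- sp$val[[1]]$image
p_liver  <- model_predict(model, img, "Segment the Liver region")
p_kidney <- model_predict(model, img, "Identify the Right kidney")
compute_metrics(p_liver, sp$val[[1]]$masks$liver)$dice
```

On this 30-epoch toy run the evaluation line prints

```
iou=0.7167  dice=0.7941  f1=0.7941  map=0.8833  hd=6.5470  kappa=0.7879
specificity=0.9951  recall=0.7568  precision=0.8525  pixel_accuracy=0.9868
```

and the final `compute_metrics()` call returns a liver Dice of 0.967 on
that validation scene. The mean Dice of 0.79 is a mid-training snapshot
across all four organ prompts (the small kidneys are hardest); the full
protocol below pushes it higher. The two prompts return different masks
for the same image; that difference is the conditioning pathway at work. The packaged experiment
`prompt_conditioning_experiment()` runs the full desk-scale protocol
(120 scenes, 45 epochs) where matched-prompt validation Dice reaches ≈ 0.9
while swapped-prompt Dice collapses to ≈ 0.

The command-line interface wraps the same functions:

```sh
Rscript inst/cli/promptseg.R synth --task multi_organ --n 50 --seed 7 --out ds
Rscript inst/cli/promptseg.R train --data ds --out run --loss tversky \
    --epochs 45 --lr 2e-3 --seed 0
Rscript inst/cli/promptseg.R infer --checkpoint run --image ds/images/s0001.png \
    --prompt "Segment the meningioma" --out case1
```

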