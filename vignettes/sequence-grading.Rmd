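---
title: "Sequence-based grading of CLE image streams: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based grading of CLE image streams: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `cleseq`, the assumptions
behind them, the design choices made where the design was genuinely open,
and what the synthetic benchmark does and does not establish.

## The classification problem

A confocal laser endomicroscopy (CLE) examination is an ordered stream of
grayscale frames acquired at roughly one frame per 1.3 s from tissue
contact during brain tumor surgery. Fluorescein brightens the extracellular
space; cells appear as dark silhouettes. The task is binary: assign the
whole examination a high-grade or low-grade label. The unit of prediction
is the examination (sequence), not the frame, because the evidence experts
use is partly temporal: flowing uniform silhouettes are red blood cells
(RBCs), static ones are tumor cells, and frames ruined by motion artifacts
can be discounted when neighboring frames are clean.

## The sequence model

Let $x_1,\dots,x_T$ be the frames after preprocessing. The model is the
composition:

1. **Per-frame embedding.** A visual backbone maps each frame independently
   to $v_t \in \mathbb{R}^D$. No temporal mixing happens here: the feature
   stage is frame-permutation-equivariant by construction, and a test
   asserts it.
2. **Standardization and projection.** Embeddings are z-scored per
   dimension with mean and standard deviation fitted on the *training*
   frames and stored in the model, then projected linearly to the model
   width $d$. The standardization is part of the model: raw backbone
   activations can be orders of magnitude smaller than the positional
   encoding that is added next, and attention logits would otherwise be
   dominated by position alone.
3. **Positional encoding.** Sinusoidal by default,
   $PE(t)_{2i} = \sin(t/10000^{2i/d})$, $PE(t)_{2i+1} = \cos(\cdot)$, with
   zero-based positions; parameter-free and length-extrapolating. A learned
   per-position table is available (`positional_encoding = "learned"`).
4. **Transformer encoder.** Two encoder blocks (the default
   `n_encoder_layers = 2`), each multihead self-attention followed by a
   position-wise feedforward, with residual connections and post-norm layer
   normalization. "Two multihead self-attention layers" is read as two
   encoder blocks rather than two attention sublayers inside one block.
   Defaults `n_heads = 4`, `model_dim = 32`, `feedforward_dim = 64`,
   `dropout = 0.1` are configuration choices sized to the tiny backbone's
   32-dimensional features; they are exposed, not baked in.
5. **Temporal aggregation.** A same-padded 1-D convolution along the time
   axis (`conv_kernel = 3`, odd by contract) captures local temporal
   patterns such as frame-to-frame change; a ReLU (`conv_activation`,
   default `"relu"`) rectifies the filter responses so that signed
   frame-difference filters do not cancel under the subsequent masked
   global average pooling, which compresses the sequence into a single
   global temporal embedding of length `conv_channels = 32`. With
   `conv_kernel = 1`, an identity filter and `conv_activation =
   "identity"`, this stage reduces exactly to the temporal mean — the
   bag-of-frames ablation reference, asserted by an arithmetic oracle test.
6. **Head.** A fully connected layer and softmax over {high, low}.

Variable-length batches are handled by padding plus a boolean mask: padded
positions are excluded from attention as keys, zeroed before the temporal
convolution (so they cannot leak through the kernel support), and excluded
from the pooling mean. The contract that padded frames never alter the
outputs at real positions is tested to 1e-5.

**The frame-based baseline** applies a per-frame softmax head to the same
embeddings and aggregates per-frame votes by majority, breaking ties toward
high grade — the tie-break privileges sensitivity in a screening context,
and the rule is documented because any rule must pick a side. A
`mean_prob` aggregation is also available. Both rules are symmetric in
frame order, so the baseline is permutation-invariant, while the sequence
model is not; this asymmetry is the central testable difference between the
two approaches.

## Training

Cross-entropy loss against the examination label, Adam optimization
(mini-batches of sequences for the temporal model, full batch for the
baseline head), backbone frozen. The backbone is kept frozen by default
because the temporal module is the object of study and frozen features make
CPU-scale training practical; a `frozen` flag records the intent, and
fine-tuning is simply not implemented. All randomness — weight
initialization (Glorot for linear maps, He for convolutions), shuffling,
dropout — derives from the training seed, and identical seeds reproduce
identical loss trajectories bit for bit. Divergence (non-finite loss)
aborts with a diagnostic rather than continuing silently. Early stopping
monitors the training loss with a configurable patience, since the
protocol has no validation split.

The whole network core — attention, layer norm, temporal convolution,
softmax, and all their gradients — is written in plain R matrix algebra.
Correctness rests on finite-difference gradient checks (relative error
below 1e-3 across every parameter tensor, under both positional-encoding
modes and both conv activations) plus closed-form oracles: single-token
attention reduces to the value path, the kernel-1 identity convolution to
the temporal mean, softmax and cross-entropy to their textbook values.

## Splits

`make_splits()` reproduces the study protocol: training size
$= \mathrm{round}(f \cdot N)$ sequences (105 sequences at $f = 0.743$
give 78/27). Sequence-level randomization matches the original protocol
but can place sequences of one patient on both sides; the default here is
therefore case-level grouping, which cuts at the case boundary closest to
the target size. Whether the study stratified by class is unstated;
`stratify = TRUE` randomizes within grade strata so both sides retain both
classes by construction, and the package's own experiments use it. A split
that strands a class on either side is an error, never a silent
degeneracy.

## The synthetic benchmark

No public CLE corpus exists, so the simulator stands in for patient data.
It emulates, with exact ground-truth annotations:

- a flat fluorescein background (`background_level`, default 0.65) with
  Gaussian pixel noise (`background_noise_sd`, 0.02);
- tumor cells as dark anti-aliased ellipses: Poisson counts with intensity
  `cell_density` (per pixel²), truncated-normal radii
  (`cell_radius_mean` = 3 px; `cell_radius_sd` is the pleomorphism scale),
  shape irregularity via `cell_eccentricity_sd`, and an intensity drop of
  `silhouette_contrast` (0.45) below the local background, anti-aliased
  over a ~1 px soft edge via an approximate signed distance; overlapping
  silhouettes combine by maximum coverage so they never double-darken;
- RBCs as small uniform discs that translate rigidly by
  `rbc_flow_velocity` pixels per frame along a per-sequence random
  direction, wrapping toroidally at the edges — the wrap keeps the
  annotated RBC count constant, a deliberate testability choice;
- motion artifacts as a directional box blur (length 7, horizontal or
  vertical) applied to whole frames flagged with probability
  `motion_artifact_prob` (default 0.5, the clinically reported rate);
- optional high-grade features: necrosis as irregular low-intensity blob
  clusters, microvascular proliferation as bright branching random-walk
  curves — the imaging literature names these features but not their image
  statistics, so both are simple parametric stand-ins behind flags;
- frames written as 8-bit PNG by default (16-bit TIFF optional), with
  intensities quantized before writing so a written dataset re-reads
  exactly and regeneration under one seed is byte-identical.

Grade profiles override only generative parameters, never seeds or frame
geometry, so label information cannot leak through bookkeeping. Three
presets define the package's study conditions:

- `"separated"`: hypercellular, pleomorphic high grade (density 0.012 px⁻²,
  radius SD 1.5, eccentricity SD 0.3) against sparse uniform low grade
  (0.003, 0.2, 0.03). The separation is deliberately strong — roughly a
  fourfold density ratio — so that per-frame appearance nearly determines
  the class and a competent pipeline should recover it almost perfectly;
  this preset calibrates the parameter-recovery experiment.
- `"rbc_confound"`: both classes draw the same expected number of
  identically sized silhouettes per frame (density 0.006 px⁻², radius
  2.2 px); in high-grade sequences they are static tumor cells, in
  low-grade sequences flowing RBCs (4 px/frame). Single-frame statistics
  are class-uninformative by construction — a logistic fit on annotated
  per-frame counts performs at chance, which a test asserts — so only
  temporal reasoning can separate the classes.
- `"matched"`: identical parameters for both labels; Bayes accuracy is
  50%, used to check that the pipeline does not hallucinate separation.

What passing these benchmarks does **not** show: the simulator's image
statistics are far simpler than real CLE (no probe-pressure effects, no
fluorescein pharmacokinetics, no histoarchitectural texture, no device
differences beyond frame size), the tiny backbone is randomly initialized
rather than ImageNet-pretrained, and the corpus is balanced by
construction. Synthetic results demonstrate that the machinery is correct
and that temporal modeling recovers temporal signal; they say nothing
quantitative about accuracy on real patient data.

## The backbone

`tiny_test_cnn` is three 3×3 stride-2 convolution blocks (1→8→8→8
channels, He-initialized from a seed, ReLU) followed by average pooling
over a 2×2 grid of spatial quadrants, giving 8 channels × 4 regions = 32
dimensions. The coarse spatial pooling — rather than a strict global
average — is deliberate: a fully translation-invariant embedding would
erase silhouette *positions*, and with them the only class signal in the
RBC-confound design (motion). Quadrant pooling keeps gross layout visible
to the temporal model while remaining compact. The four ImageNet families
(Inception-ResNet-V2, ResNet50, VGG16, vision transformer) are registered
with their conventional input sizes and embedding dimensions (299/1536,
224/2048, 224/4096, 224/768); running them requires externally supplied
pretrained weights and is out of scope for the self-contained test path.
Embeddings are taken at the penultimate pooled activation by convention;
the study's layer choice is unstated.

## Preprocessing

Intensity normalization divides by the dtype maximum (`2^bits - 1`),
never per-image min–max: per-image scaling would equalize overall
brightness across frames, destroying a diagnostic signal (fluorescein
leakage differs between tissues). Resizing is bilinear with half-pixel
centers (no corner alignment), so constants are preserved exactly and
outputs stay within the input range to 1e-6. Non-square frames are
aspect-preserving-resized and padded to square at the frame's median
intensity, an approximation of the local background; the alternative
(center-cropping) discards tissue and was rejected. Grayscale frames are
replicated across channels to meet 3-channel backbone contracts; the
channel mean inverts the replication exactly. Preprocessing never
reorders, drops, or duplicates frames — whole-sequence exclusion of
artifact-ruined examinations is a curation step outside this package, and
single-frame artifact filtering is deliberately absent to preserve
sequence integrity.

## Evaluation

Positive class = high grade. Accuracy, sensitivity, specificity, PPV and
NPV are computed from confusion counts at full precision and displayed with
half-up integer rounding (base R's round-half-even would disagree with
printed tables on exact halves). A metric with a zero denominator is `NA`
and flagged undefined, never silently 0. Multi-split experiments aggregate
by the arithmetic mean of per-split accuracies. The identity
$\mathrm{acc} = (\mathrm{sens} \cdot P + \mathrm{spec} \cdot N)/(P+N)$ is
asserted over random counts as a cross-check.

## Class activation maps

Gradient-weighted CAM: the gradient of the target-class logit is taken with
respect to the last conv block's post-ReLU activations (for the sequence
model the gradient path runs through the full temporal head with the frame
treated as a single-frame sequence; per-frame maps only, since temporal
attribution is out of scope). Channels are weighted by their spatially
averaged gradients; the weighted sum is rectified, min–max normalized to
[0, 1] — a constant map normalizes to all zeros by convention — and
bilinearly upsampled to frame resolution. Overlays blend a blue→red
colormap (warm = relevant) onto the grayscale frame. On simulated frames
whose high-grade evidence is an isolated hypercellular cluster, the map's
center of mass falls inside the cluster's bounding box in at least 70% of
correctly classified high-grade test frames — a weak localization check;
pixelwise agreement with any particular figure is not claimed.

## Numerical choices and degenerate inputs

- Layer-norm epsilon 1e-5; attention masking via −∞ logits before the row
  softmax (masked keys receive exactly zero weight and zero gradient).
- Cross-entropy clamps the true-class probability at 1e-12.
- Probability normalization is asserted to 1e-6 on every prediction.
- Single-frame sequences are valid (attention weight 1, conv over one
  padded window); all-padded sequences and empty sequences are errors.
- Intensity assembly clips to [0, 1], never wraps.
- Per-sequence seeds are derived from the master seed by a fixed affine
  map modulo a 31-bit prime, keeping all seeds valid R integers.

## Problem sizes

The package's experiments use 16 cases × 5 sequences (80 examinations,
split 60/20 by case with stratification), 64×64-pixel frames, 12 frames
per sequence, and the tiny backbone, with Adam at learning rate 1e-3
(batch 8, 60 epochs) for the temporal model and 1e-2 (full batch, 200
epochs) for the baseline head; the RBC-confound comparison is repeated
over three seeds and summarized by medians. These sizes were chosen so a
complete experiment runs in well under a minute on one CPU core while
keeping 20 held-out examinations (5-percentage-point accuracy
granularity). Defaults in `train_config()` (learning rate 1e-4, batch 4,
100 epochs) are deliberately conservative starting points for users' own
datasets.

## Known limitations

- The simulator is a phenomenological model, not an optical one; see the
  benchmark caveats above.
- ImageNet backbones are interface-registered but not runnable offline.
- Training is CPU-bound plain R; it is sized for desk-scale experiments
  (hundreds of short sequences), not clinical corpora.
- The baseline's majority vote on near-balanced frame votes is sensitive
  to the tie-break; both aggregation rules are exposed so users can check
  robustness.
- Binary grading only; multi-class WHO grades and recurrent (LSTM)
  temporal models are out of scope.
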