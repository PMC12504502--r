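---
title: "Reconstruction-assisted lesion segmentation: model, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction-assisted lesion segmentation: model, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfel)
```

## The problem and the model

Lesion segmentation networks trained purely on mask supervision learn strong
object-level semantics but tend to discard the pixel-level texture and
boundary detail that determines where a lesion actually ends. `mfel` couples
the segmentation task with a self-supervised image-reconstruction task so
that the two exchange exactly that information. The model has two branches
over a shared three-stage convolutional pyramid architecture:

* **Reconstruction branch.** During training the ground-truth mask $I_m$
  splits the image $I_s$ into a foreground image $I_f = I_s \otimes I_m$ and
  a background image $I_b = I_s \otimes (1 - I_m)$. Three encoders (for
  $I_f$, $I_b$ and $I_s$) produce feature pyramids $F_f^i, F_b^i, F_r^i$,
  $i = 1,2,3$. At each level an *adaptive feature modulation* module
  concatenates the three features on channels, pools globally, and maps the
  pooled vector through two parallel 1×1-conv streams to per-channel
  calibration parameters, applied as
  $\hat F_r^i = (1 + \alpha)\,F_r^i + \beta$. Three independent mirror
  decoders reconstruct $I_f$, $I_b$ and $I_s$ (the last from the calibrated
  pyramid), each penalized by a mean-reduced $\ell_1$ loss
  ($L_f, L_b, L_s$).
* **Segmentation branch.** A fourth encoder produces segmentation features
  $F_s^i$. At each level a *bi-directional fusion* module computes paired
  cross-attentions, $\mathrm{Attn}_r = \mathrm{softmax}(Q_s K_r^\top / \sqrt d)$
  and $\mathrm{Attn}_s = \mathrm{softmax}(Q_r K_s^\top / \sqrt d)$, where each
  stream queries the other; the retrieved values are 1×1-convolved, added
  residually to each stream's own feature, and the two enhanced features
  are concatenated and reduced back to $C_i$ channels. The deepest fused
  feature is flattened to a raster token sequence, split into four
  contiguous groups, and each group passes through one weight-shared
  *selective state-space scan* with a learnable $\gamma$-scaled residual;
  the concatenated sequence is layer-normalized, linearly projected, and
  reshaped. A U-Net-style head decodes the fused pyramid to a per-pixel
  foreground probability.

The composite objective is the unit-weight sum
$L_\text{total} = (L_f + L_b + L_s) + (L_\text{BCE} + L_\text{Dice})$.
Evaluation uses precision, recall, F1 and IoU from pixel confusion counts.

## Training-time versus inference-time asymmetry

The foreground/background decomposition needs the ground-truth mask, which
exists only during training. The package therefore treats the foreground
and background reconstructions and the feature calibration as training-only
devices: at inference only the medical-image encoder runs and its
*uncalibrated* pyramid feeds the fusion modules. To keep the feature
distribution the segmentation branch sees consistent between the two modes,
the calibration output layers are zero-initialized, so $(\alpha, \beta) =
(0, 0)$ at the start and calibration begins as the identity
($\hat F_r^i \equiv F_r^i$). Whether the original design runs the
reconstruction sub-branches at test time with a predicted mask is not
something the method's description pins down; the training-only reading
requires no second forward pass and keeps the identity form of the
calibration exact.

Under the `no_fiir` ablation the whole reconstruction branch is absent.
Since the fusion modules then have no second stream, the segmentation
pyramid passes to the head unfused; the logged reconstruction losses are
identically zero and $L_\text{total} = L_\text{mask}$.

## Resolved ambiguities

Several points of the method are ambiguous as printed; the package resolves
them as follows.

* **Attention scaling.** The attention formula divides the logits by the
  head dimension $d$. The package defaults to the numerically safer
  $\sqrt d$ and exposes `attention_scale = "d"` for the literal form.
* **Cross-retrieval pattern.** The printed fusion equation references an
  undefined attention map. The only internally consistent reading of "each
  feature guides the other" is the standard cross-retrieval: the
  segmentation-guided map retrieves reconstruction values (added to the
  segmentation feature) and vice versa. That is what `bfm_fuse()` computes.
* **Token grouping.** The sequence block's split is token-wise (four
  contiguous raster quarters of the deepest feature map), not channel-wise;
  splitting and concatenation are exact inverses, which the tests assert.
* **Per-level application.** Both the modulation and the fusion modules are
  applied at all three pyramid levels, following the per-level index in
  their definition.
* **Normalization.** The architecture description calls for convolution +
  normalization + nonlinearity blocks without naming the normalizer. The
  package uses instance normalization (per channel, over space, learnable
  gain/bias), the standard choice for small-batch medical segmentation;
  per-pixel channel normalization was rejected because at the stem it
  nearly cancels absolute intensity, the dominant cue in lesion images.
  Token sequences inside the mamba block use ordinary layer normalization.
* **Warm-up.** The schedule's warm-up length is unstated; the package uses
  5 epochs and starts the ramp at `lr_final`.
* **$\gamma$ initialization.** The residual scale in the sequence block is
  a learnable scalar initialized at 1.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `epochs`, `batch_size` | 150, 4 | published training regime |
| `lr_init`, `lr_final` | 1e-3, 1e-5 | Adam, warm-up + cosine annealing |
| `warmup_epochs` | 5 | linear ramp length (epochs) |
| `working_size` | 256 (dermoscopy), 128 (histology) | square resolution, px |
| `stage_channels` | 32, 64, 128 | encoder widths per pyramid level |
| `state_dim` | 16 | selective-scan state size |
| `ablation` | `"full"` | one of the seven studied variants |
| `reduction` | `"mean"` | $\ell_1$ reduction (`"sum"` for the raw norm) |

Adam uses the ecosystem momentum defaults ($\beta_1 = 0.9$,
$\beta_2 = 0.999$); no augmentation, weight decay or gradient clipping is
applied, since the training regime specifies none.

## Numerical engine

No deep-learning framework is available to (or desirable for) a pure-R
package of this size, so `mfel` ships its own reverse-mode autodiff on
dense arrays: convolutions are one im2col gather plus one BLAS matrix
product each way, the selective scan implements the hand-derived adjoint
recurrence, and every operator's gradient is verified against central
finite differences in the test suite. The recurrence itself is additionally
checked against a brute-force unrolled oracle on random sequences. The
discretization step of the scan is kept positive through a softplus, the
state matrix negative through $A = -e^{A_{\log}}$ (initialized to
$-1, \dots, -N$ per channel), and probabilities are clamped at $10^{-7}$
inside the cross-entropy. Degenerate metric cases follow the standard
benchmark convention: both masks empty gives all metrics 1, a prediction
with no true positive against a nonempty truth gives 0.

Training runs one sample at a time and accumulates gradients across the
minibatch, which bounds peak memory by a single sample's graph; with fixed
seeds and the single-threaded numerics used here, loss trajectories are
bitwise reproducible and checkpoint/resume preserves them exactly (RNG
state is stored in the checkpoint).

## What the synthetic fixtures emulate

`generate_fixtures()` draws blob-shaped lesions (ellipses with low-order
Fourier boundary deformation) with a mean foreground-background intensity
separation of 0.35, smooth background and foreground textures, Gaussian
boundary blur (σ = 1 px), additive Gaussian noise (σ = 0.02), and
optionally dark curvilinear hair-like strokes — the classic dermoscopy
distractor. Masks are the un-blurred blob supports. The generator is
integer-seeded and bit-reproducible.

These fixtures capture the geometry of the task (compact deformable
targets, blurred boundaries, texture contrast, distractors) but not the
full appearance diversity of real dermoscopy or histology: no illumination
gradients, color calibration differences, multi-modal lesion textures, or
annotation noise. Convergence on the fixtures demonstrates that the
architecture, gradients and optimization work end to end; it says nothing
about clinical-grade accuracy on real benchmarks, which require the
original datasets and full-scale training.

## Desk-scale problem sizes

The package's own experiments (test suite and `scripts/acceptance.R`) run
at deliberately small sizes chosen as the smallest that still exercise
every component meaningfully: 64×64 fixtures, encoder widths [16, 32, 64],
batch 1, 50 epochs (400 optimizer steps) for the convergence experiment
(single-sample batches maximize the number of Adam updates per unit of
compute, which is what desk-scale memorization needs);
32×32 and widths [4, 8, 8] for smoke tests of all seven ablation variants.
The published regime (256 px, widths [32, 64, 128], batch 4, 150 epochs)
remains the package default for real use.

## Known limitations

* Sequential (non-parallel) scan and pure-R convolutions limit throughput
  to desk-scale experiments; the contract is the recurrence and the
  gradients, not kernel speed.
* Single-head attention per level; head count was unspecified and one head
  suffices at these widths.
* Fixtures are RGB-correlated (near-gray textures); color-specific failure
  modes of real lesions are not represented.
* Benchmark-scale results on GLAS/ISIC/PH2 are out of scope: they require
  the external datasets and GPU-scale training.
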