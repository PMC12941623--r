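---
title: "SWAU-Net: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SWAU-Net: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The forecasting problem

Geographic atrophy (GA) is the advanced non-neovascular form of age-related
macular degeneration: sharply demarcated atrophic lesions of the retinal
pigment epithelium that appear dark (hypoautofluorescent) on fundus
autofluorescence (FAF) imaging and expand irreversibly over time. Given a
patient's registered FAF frames and graded lesion masks at months 0, 6 and
12, the task is to forecast the lesion mask and the *growth mask* — the
pixels newly atrophic since the previous visit — at the next visits. Growth
masks are thin, irregular bands at the junctional zone, so they are far
harder to predict than the (largely persistent) lesion itself, and they are
the clinically informative quantity: enlargement rate is the standard trial
endpoint.

The package implements SWAU-Net, a hybrid CNN–Transformer encoder–decoder
built around three priors suited to the low-data regime of longitudinal
ophthalmic imaging:

1. **A regularized U-Net backbone** that preserves sparse high-frequency
   boundary detail (gated residual blocks, channel-fusion bottlenecks).
2. **Temporal stationarity** via a weight-shared sliding-window attention
   (SWA) core: one parameter set applied to all shifted 3-visit windows, so
   the network must learn a time-invariant transition rule instead of
   memorizing visit indices.
3. **Decoupled dynamics**: a dedicated 3-level U-Net (DynNet) evolves the
   integrated latent state one visit forward, separating state estimation
   from forecasting.

## Architecture

Inputs are per-visit 3-channel frames (FAF, lesion mask, growth mask) at
256×256 (reference) resolution. The encoder has five feature levels L1–L5
with channels $C, 2C, 4C, 8C, 16C$ ($C = 16$) and four stride-2
down-sampling stages, giving a 16×16×256 bottleneck; L4 is 32×32×128.

* **Dual-path stems.** FAF and the two mask channels pass through separate
  two-convolution stems at width $C/2$ before concatenation, so diffuse
  intensity noise does not pollute the crisp mask geometry.
* **Gated residual block (GRB).** $y = R(x) + \sigma(G(x)) \odot
  H(x - \mathrm{blur}(x))$ with $R$ a standard two-convolution residual
  branch, blur a 3×3 box filter, $H$ one 3×3 convolution, and $G$ a 1×1
  per-channel gate. The high-frequency side path counteracts convolutional
  over-smoothing at the growth front.
* **Channel-fusion bottleneck (CFB).** A residual 1×1–3×3–1×1 stack with 2×
  inner channel compression, applied at every level as a cross-channel
  regularizer.
* **Spatial self-attention** (4-head dot-product over flattened spatial
  tokens, residual) at L4 and L5, and at the DynNet bottleneck.

### Sliding-window attention

Refined features $F_0, F_1, F_2$ are aggregated into latent states through
three zero-padded windows,

$$M_0 = \mathrm{SWA}(0, 0, F_0),\quad M_1 = \mathrm{SWA}(0, F_0, F_1),\quad
M_2 = \mathrm{SWA}(F_0, F_1, F_2),$$

with **one** shared parameter set. Attention within a window is unmasked;
causality is enforced entirely by the windowing, which the test suite
verifies bit-exactly (perturbing visit 2 cannot change the month-6 or
month-12 forecast). At L4/L5 attention is axially factorized into a
time–width pass (each image row is a batch element, $3W$ tokens) and a
time–height pass, each with learned positional embeddings over the 3 time
slots and the spatial axis. A gated convolutional block over
(width, height, time) — channel concatenation of the three frames, a 1×1
GLU, a 3×3 convolution — restores cross-axis interactions; it is scaled by
a trainable scalar initialized at exactly 0, so at initialization it is
bit-exactly inert. At L1–L3 a weight-shared 3-frame convolution mixer
enforces temporal smoothness instead of attention; macro-residual
connections $M = \alpha F_t + \beta\,\mathrm{out}$ (learnable scalars,
initialized at 1) fuse the temporal output with the current visit's
encoder features at every level.

### DynNet and decoder

DynNet resamples all five levels of $M$ onto the L3 grid (parameter-free
pooling/upsampling followed by 1×1 projections), fuses them, runs a 3-level
U-Net with spatial attention at its bottleneck, and redistributes the
output to every level as a residual update $E = M + \Delta$. The decoder
applies a CFB per level and a U-Net decoder with the anchor visit's
encoder skips — a single 3×3 fusion convolution per level — ending in a
3-channel head: FAF (sigmoid), lesion logits, growth logits. The
reconstruction path decodes $M$ directly (no DynNet) through the **same**
decoder, sharing weights with the prediction path to limit parameters, per
the two-path multi-task design.

With $C = 16$ and DynNet base width $2C = 32$ the reference model has
8,328,055 trainable parameters — 8.3 M at one decimal. The test suite
verifies this count against an independent closed-form enumeration of the
same wiring.

### Ablation variants

`listVariants()` builds the eight ablations on the shared backbone:
spatial-attention removal, CFB removal (identity passthrough — the residual
skip without the stack), three temporal-core replacements (unshared causal
axial attention, per-level convolutional aggregation, two stacked ConvLSTM
cells at L4/L5 with the shallow mixer retained), DynNet removal (decoding
directly from $M$, no reconstruction objective), and the two training-level
switches (no pretraining, no augmentation). The unshared-attention variant
replicates the full temporal core per window, so its temporal-core
parameter count is exactly three times the reference — an auditable
consequence of removing weight sharing.

## Training

The hybrid objective is
$L = L_{\mathrm{pred}} + \lambda_{\mathrm{recon}} L_{\mathrm{recon}}$,
$\lambda_{\mathrm{recon}} < 0.5$ (enforced), each component combining a
soft Dice loss on the lesion mask, a soft Dice loss on the growth mask
weighted by `growthWeight`, a small BCE stabilizer on both logit channels,
and an L1 term on the FAF channel, averaged per frame and then over the
three forecast frames. The component magnitudes are package choices
(defaults 0.25 / 4 / 0.1 / 1): the growth weight implements "weighted
heavily on the sparse growth regions", and the BCE term keeps gradients
alive where the Dice terms saturate. BCE is applied to both mask channels.

Training is two-stage: 50 epochs of synthetic pretraining at learning rate
1e-3, then 60 fine-tuning epochs at 1e-4 (Adam, dropout 0.2 on attention
branches, gradient accumulation of `batchSize × accumulationSteps` samples
per update — defaults 2 × 4). When no clinical data are supplied,
fine-tuning uses a disjoint synthetic split (twice the validation
fraction); a fixed 10% of sequences is held out for validation throughout.
Online augmentation samples one geometric transform per sequence (rotation
±15°, horizontal flip p = 0.5, zoom 0.9–1.1 — ranges are package choices)
applied identically to all frames and channels, with nearest-neighbour
resampling and re-binarization for masks and growth masks recomputed from
the transformed lesion masks so the growth identity holds exactly; FAF-only
corruption (gamma jitter, additive noise, dark blotches) is per-frame.

### Numerical choices

* The network contains no normalization layers; instead every residual
  side branch (GRB second convolution and high-frequency path, CFB output
  projection, attention output projections, DynNet redistribution) is
  initialized at exactly zero, making each block an identity map at
  initialization. Activations then stay at unit scale through the deep
  unnormalized graph, which is what makes training stable at these depths;
  gradients reach the zeroed weights through their inputs on the first
  update.
* Masks are binarized at probability 0.5. Empty-vs-empty masks score
  Dice 1 (growth masks can legitimately be empty).
* The Dice smoothing constant is 1; the corrected t-test handles the
  zero-variance fold vector explicitly (p = 1 at zero mean, p = 0 with a
  degeneracy note otherwise).
* All convolutions use zero padding; dilation kernels with a single active
  pixel are treated as the identity.
* The whole model, its reverse-mode autodiff tape and Adam are implemented
  in R with C++ im2col/BLAS convolution kernels; gradients are validated
  in the test suite against central finite differences and the
  convolution against a brute-force oracle.

## The synthetic growth simulator

The simulator provides the pretraining corpus (default: 2000 four-frame
sequences, 8000 frames, 256×256) and the fixture generator for tests. Per
sequence: a lesion is seeded by thresholding a 1–4-peak Gaussian field at
50% of its maximum (relative thresholding keeps the initial area
scale-free); growth applies a one-sided half-elliptical directional
dilation (radius 2–8 px per step along a per-sequence anisotropy
direction) followed by three stochastic erosion/dilation cycles with small
disc elements, then a union with the previous mask — growth is monotone
because clinical GA does not regress, and the growth-mask identity
$\mathrm{growth}_i = \mathrm{lesion}_i \setminus \mathrm{lesion}_{i-1}$
(all-zero at the first visit, which has no prior) holds exactly by
construction. FAF rendering places the dark lesion (0.12) on a textured
bright background (0.6), brightens a thin junctional rim (×1.15), draws
3–8 persistent vessel-like random-walk tracks that are held fixed across a
sequence (they are anatomy the model must learn to ignore, not noise), and
adds Gaussian noise amplified ×2 outside the central disc. None of these
magnitudes are clinical measurements; they are package choices that
reproduce the qualitative regimes of real FAF — sparse jagged fronts,
anisotropic expansion, dark confusable structures, peripheral noise.

What passing tests on this corpus do **not** show: photometric realism,
device characteristics, registration artifacts, clinically calibrated
growth rates (the 2.1 mm²/yr natural-history figure is not a simulator
target), or transfer to real FAF. The clinical-data path
(`preprocessClinicalFrame`: right-eye horizontal flip, symmetric
zero-padding of the 768×868 frame to square — aspect handling is
unstated upstream, padding preserves geometry — then bilinear/nearest
resize to 256) is an interface, not a tested claim about clinical
performance.

## Evaluation statistics

`diceCoefficient` is $2|P \cap T| / (|P| + |T|)$. Cross-validation follows
the cohort protocol: a randomized eye-level split into k = 5 folds whose
sizes differ by at most one (66 eyes give 13/13/13/13/14); per fold the
epoch-wise **median** DSC over test eyes is averaged over the last 10
epochs; cohort summaries are mean ± SD over folds. Model pairs are
compared with the Nadeau–Bengio corrected resampled t-test,
$t = \bar d / \sqrt{(1/k + n_{\mathrm{test}}/n_{\mathrm{train}})\, s_d^2}$
with $k - 1$ degrees of freedom ($r = 1/4$ for 5-fold CV); at $r = 0$ it
reduces exactly to the classical paired t-test, which the tests check to
1e-10. The paired differences are per-fold summary scores (the CV-aware
correction pairs at fold level). Nine pairwise comparisons against the
reference give the Bonferroni threshold $0.05/9 = 0.0056$.

## Problem sizes used by the test suite

Structural tests run at the smallest legal configuration (32² input,
C = 4). The end-to-end learning check runs the full two-stage protocol at
a scaled-down study size chosen once: 64² input, C = 8, 200 synthetic
sequences with simulator length parameters scaled by 64/256, 5 + 5 epochs,
fixed seeds. Its thresholds (held-out mask DSC > 0.80, growth DSC > 0.35,
beating the empty-growth persistence baseline) are implementation sanity
floors for synthetic data, not clinical claims. Full-scale clinical
numbers require the 66-eye cohort, which is not distributable with the
package.

## Known limitations

* Fixed 3-visit windows and nominal 6-month intervals; irregular visit
  spacing is out of scope (a continuous-time extension would change the
  core).
* The R/C++ training path is single-threaded and sized for the scaled-down
  corpus; full-scale pretraining (2000 × 256² sequences) is supported by
  the same code but is a long-running batch job.
* The reconstruction target is each window's anchor frame (the two-path
  design reconstructs the initial frame; anchoring every window is the
  package's reading of the multi-task objective).
* Clinical preprocessing assumes upstream registration to baseline and
  reading-center-quality masks.
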