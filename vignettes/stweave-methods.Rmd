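---
title: "Multi-scale multimodal modeling of image-based spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale multimodal modeling of image-based spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

Image-based spatial transcriptomics measures, for every segmented cell $i$
in a tissue slide, a high-resolution image crop $C_i$, a gene expression
count vector $g_i \in \mathbb{R}^G$, and a spatial coordinate
$s_i = (x_i, y_i)$. stweave learns a single embedding per cell that fuses
all three, hierarchically contextualized at two coarser scales:

* **cell** — the triple $(C_i, g_i, s_i)$, with $C_i$ the minimal square
  crop that fully contains the cell's boundary polygon;
* **niche** — a non-overlapping 256-px tile of the slide (the local
  microenvironment), carrying the tile image and the *exact elementwise
  sum* of its member cells' count vectors;
* **tissue** — a 1024-px tile summarizing niches and their grid positions,
  again with exact pooled counts.

The dataset builder starts from a z-stack image, takes the per-pixel
maximum-intensity projection over z, and min–max normalizes to 8-bit
(round-half-to-even; a constant image maps to zero). Cells are assigned to
exactly one niche by their centroid under the floor rule
(`row = floor(y / tile)`), so gene mass is conserved exactly at every
scale — an invariant the test suite checks with integer equality. All pixel
coordinates are 0-based with x = column and y = row, and tiles are
half-open `[origin, origin + tile)`. Border tiles are zero-padded rather
than discarded so no cell is lost; empty tiles are dropped. Records
serialize into an append-only key-value store with zero-padded decimal keys
joined to the slide id, so lexicographic key order equals write order.

# Encoders and cross-attention fusion

Images are encoded by small vision transformers: non-overlapping patches
are linearly projected to width $D$, a learnable `[CLS]` token is
prepended, learned positional embeddings are added, and pre-norm
self-attention blocks follow. The gene vector is encoded *per gene*:
token $j$ equals `gene_embedding_j * log1p(g_j) + mlp(log1p(g_j))`, which
makes the token matrix local in the genes (changing one count changes one
row) and lets a zero count contribute only the shared `mlp(0)` term. The
gene backbone is pluggable — any callable mapping a count vector to an
$N_\mathrm{gene} \times D$ matrix can replace the built-in encoder, so a
pretrained external gene model can be dropped in.

Fusion is cross-attention throughout:

* **cell**: the image token sequence queries the gene token matrix
  (keys = values = gene tokens); after a residual feed-forward, the fused
  `[CLS]` row is the cell embedding $z^c_i$. Reading `[CLS]` is our
  choice of how the fused token matrix becomes one vector; attention over
  keys makes $z^c$ exactly invariant to gene-token order.
* **niche**: the arithmetic mean $\bar z$ of member cell embeddings is a
  single query over the niche image tokens. We deliberately use the pooled
  context as the *query* and the imagery as keys/values — the alternative
  orientation (image tokens as queries) cannot produce a single
  $D$-vector, which the hierarchy requires.
* **tissue**: niche embeddings plus fixed 2-D sinusoidal positional
  embeddings at their grid coordinates pass through a transformer; each
  niche embedding then queries that token sequence.
* **unified**: $z^c_i$ is the sole query over the stacked
  $(z^c_i, z^n_j, z^t_k)$; missing levels fall back to the remaining keys.
  One cross-attention block per fusion site is used at this scale; depth is
  configurable.

Every fusion site is tested against an independent dense loop-based
attention oracle at dimensions of eight and below, at $10^{-5}$.

# Self-supervised objectives

Training needs no labels. Two decoders reconstruct the inputs from the
unified embedding:

* **pixel reconstruction** — a linear expansion of $z$ to a coarse channel
  grid followed by transposed-conv upsampling; the loss is the mean squared
  pixel error on the $[0,1]$ scale (mean over pixels and batch — the mean
  convention is pinned by a hand-computed test: a uniform offset $\delta$
  costs exactly $\delta^2$);
* **masked-gene regression** — 15% of genes are masked per example; all
  learnable gene queries cross-attend to $z$ (a single memory token) and a
  per-gene linear head predicts `log1p` expression; the MSE is taken over
  masked positions only, so unmasked targets provably never affect the
  loss. Genes are continuous counts, so we regress rather than
  classify; masking plus regression keeps the spirit of masked-language
  pretraining without inventing a token vocabulary.

The total loss is $\lambda_\mathrm{cell}\,L_\mathrm{img} +
\lambda_\mathrm{gene}\,L_\mathrm{gene}$ (defaults 1 and 1). A component
with zero weight is skipped entirely, so its decoder parameters stay at
initialization — a gradient-flow contract the tests assert.

During the training loop, the niche and tissue context of every cell is
recomputed *without gradients* at each epoch boundary and treated as a
constant inside the step: a cell's loss never backpropagates through other
cells' encoders, which bounds memory and makes the loop embarrassingly
simple. The cost is that context embeddings lag the encoder by at most one
epoch. Checkpoints store parameter values plus optimizer moments; resuming
at an epoch boundary (where context is recomputed anyway) reproduces the
loss trace bit-for-bit.

Optimization is AdamW with learning rate $10^{-3}$ at desk scale.
All randomness (batch order, masks, initialization) flows from explicit
integer seeds; the engine underneath is a small tape-based reverse-mode
autodiff over dense R arrays, whose gradients are verified against central
finite differences in the test suite.

# Conditional latent diffusion with importance-guided token merging

The generative decoder synthesizes cell images from a conditioning vector
$z_\mathrm{cond}$ — the unified embedding recomputed from
$(C_i, g'_i, s_i)$, where $g'$ may carry gene edits (knockout sets a count
to zero; overexpression multiplies it). Three design points matter:

* **latent space** — a convolutional autoencoder (trained first, then
  frozen) maps 64-px crops to $16 \times 16 \times 4$ latents (factor-4
  downsampling); decoding is deterministic, and training latents are
  rescaled to unit variance before diffusion (the same factor is undone at
  decode time), the usual latent-diffusion convention. Crops enter this
  pathway bilinearly resized to 64 px; at this autoencoder capacity a
  resized crop reconstructs far better than a scale-preserving
  center-padded presentation (whose sparse bright blob an MSE objective
  underweights), so resizing is the default and
  \code{crop_to_canvas()} is available when absolute cell size must stay
  visible.
* **denoiser** — a two-level U-Net on the latents with, at each
  resolution, a self-attention block and a cross-attention block over a
  single conditioning token. The conditioning vector is layer-normalized
  inside the network (so its scale cannot swamp optimization), added to
  the timestep embedding, and concatenated as broadcast input channels —
  three redundant routes that keep conditioning first-order at this model
  size. The unconditional branch replaces the token with a learned null
  embedding, trained by condition dropout (default probability 0.1; the
  shipped desk-scale runs use 0.15 because a 300-example corpus gives the
  null branch too few updates at 0.1 for stable guidance). The network
  is trained in the *clean-latent (x0) parameterization*: it regresses the
  clean latent at every noise level, and the noise prediction that
  guidance needs is recovered algebraically as $\hat\epsilon = (x_t -
  \sqrt{\bar\alpha_t}\,\hat x_0)/\sqrt{1-\bar\alpha_t}$. At desk scale
  this matters: the class-conditional component of the noise target is far
  smaller than a tiny model's prediction error, so an
  $\epsilon$-parameterized model samples images that ignore their
  condition, while the $x_0$ form keeps the conditional signal the primary
  regression target. During DDIM the per-step clean-latent estimate is
  clipped to three standard deviations of the unit-scaled training
  latents, preventing the early high-noise steps (which divide by a tiny
  $\sqrt{\bar\alpha_t}$) from leaving the data manifold.
* **guidance** — at sampling time the conditional and unconditional noise
  predictions combine as
  $\tilde\epsilon = \epsilon_u + w\,(\epsilon_c - \epsilon_u)$. We
  implement this parameterization literally, so $w = 0$ returns the
  unconditional branch, $w = 1$ the conditional one (both bitwise — tested),
  and guidance strengthens conditioning for $w > 1$.

Sampling is deterministic DDIM ($\eta = 0$) from a seeded Gaussian latent
over a linear-β schedule referenced to 1000 steps and rescaled to the
configured step count (default T = 100 at desk scale), so runs are exactly
reproducible.

**Token merging.** The per-token importance is the channel-summed absolute
guidance difference $|\epsilon_c - \epsilon_u|$, average-pooled to each
attention resolution and flattened row-major. The $M = \lceil (1-r)N
\rceil$ highest-scoring tokens become anchors (ties break toward the lower
index). Each non-anchor is *softly and non-exclusively* assigned to all
anchors with weights $\mathrm{softmax}_k(q_j \cdot k_k / \sqrt{d_h})$,
logits averaged over heads, using the attention module's own projections.
Merging replaces the token set by weighted anchor means, attention runs on
the $M$ merged tokens, and outputs are redistributed linearly (anchors
verbatim, non-anchors by their assignment weights). Merging acts only
around self-attention — the residual stream keeps length $N$ — is skipped
at the first sampling step (no importance exists yet), and importance is
recomputed once per step from the previous step's guidance difference
rather than with an extra network pass. With $r = 0$ the merged path is
byte-identical to dense attention, which the suite asserts on a toy
U-Net, and merged attention is checked against a dense oracle computed
directly from the plan.

# The synthetic slide generator

The generator is the package's ground truth. It places non-overlapping
cells by dart throwing (an overcrowded configuration fails loudly after a
retry budget), assigns each cell one of $K$ types by its nearest latent
niche center with probability $1 - \mathrm{niche\_mixing}$ (uniform
otherwise), draws counts from a negative binomial with type-specific means
(variance $\mu + \phi\mu^2$; overdispersed counts are the convention for
transcript data), and renders each cell as a rotated anisotropic Gaussian
blob with a sinusoidal texture. Radius, eccentricity and texture frequency
are affine in a projection of the type-mean expression, so morphology is an
invertible function of expression at the type level — the coupling that
makes "does the model transfer information between modalities?" a testable
question. Foreground intensity is split across z-planes with
max-one attenuation, so the maximum-intensity projection recovers the
designed blob exactly; background noise is additive and nonnegative.

Default desk-scale conditions: 4 cell types, 50 genes, 512–640-px slides,
3 z-planes, dispersion 0.1, niche mixing 0.1, 0.2125 µm/px. What the
generator does *not* emulate: real histology staining, transcript-spot
noise, segmentation errors, 3-D morphology, batch effects. Tests passing
on this data show the machinery is correct and that information genuinely
flows between modalities — not that the model meets any benchmark on real
tissue.

# Evaluation harnesses

PSNR is $10\log_{10}(\mathrm{max}^2/\mathrm{MSE})$ with identical images
reported as a capped, flagged sentinel; SSIM uses the standard 11×11
Gaussian window (σ = 1.5, $k_1 = 0.01$, $k_2 = 0.03$) over valid window
positions. Cross-modal prediction trains a two-layer perceptron and
reports mean per-target Pearson and Spearman correlation on a held-out
split, excluding (and counting) constant targets. Clustering projects
embeddings onto whitened leading principal components before seeded
k-means — the standard preprocessing in single-cell embedding analysis,
which removes the arbitrary anisotropy of a learned space — and scores
ARI and NMI (arithmetic-mean normalization). Classification uses the same
perceptron with macro-averaged F1 and precision (macro, because the
synthetic types are imbalanced by design of the spatial assignment).
A gradient-boosted-tree regression benchmark is out of scope; the
perceptron harness covers the claim that matters here — whether the
embeddings carry the information.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on synthetic
data at sizes we consider honest desk scale: a 2,000-cell corpus (four
640-px slides) for 200 pretraining steps at $D = 64$; a 300-cell two-type
corpus for the generative pathway (250 VAE steps, 120 fusion steps for
the conditioning embedding, 800 denoiser steps, 25 DDIM steps at guidance
weight 3, 64 sampled images). Attention-oracle comparisons use $10^{-5}$; merge-row
normalization $10^{-6}$; exact identities (guidance endpoints, gene-mass
conservation, determinism) are asserted bitwise. Degenerate inputs are
contracts, not surprises: empty niches, zero-area boundaries, empty
stores, all-zero gene vectors, constant images and single-key attention
all have defined behavior and tests.

# Known limitations

The dropout field in the encoder configuration is accepted but inert —
every forward pass is deterministic, which we prefer for reproducibility
at these model sizes. Niche/tissue context lags by one epoch during
pretraining (stop-gradient design). The store is a plain append-only file
pair, adequate for desk-scale corpora but not concurrent writers. The
generator's morphology link is affine and type-level; per-cell expression
noise does not feed back into rendered shape, so morphology carries type
information but not within-type expression variation.
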