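# stweave

Multi-scale multimodal representation learning and conditional generation
for image-based spatial transcriptomics, in pure R.

Image-based spatial transcriptomics assays deliver, for each segmented cell
$i$, a microscopy crop $C_i$, a gene count vector $g_i \in \mathbb{R}^G$ and
a spatial coordinate $s_i$. Most analysis treats these modalities in
isolation. stweave is for computational biologists who want the *joint*
structure: it builds matched image–expression records at three nested
scales, learns a unified per-cell embedding by cross-attention between
image patch tokens and expression-modulated gene tokens,

$$z^c_i = \mathrm{CrossAttn}(Q = X^c_i,\; K = V = x^g_i)\ \in \mathbb{R}^D,$$

contextualizes it through niche (256-px tile) and tissue (1024-px tile)
transformers, $z^n_j = \mathrm{CrossAttn}(\bar z_j, X^n_j)$ and
$z^t = \mathrm{CrossAttn}(z^n, X^t)$, and fuses all three into one vector
$z_i$ per cell. Training is fully self-supervised (pixel reconstruction
plus masked-gene regression, weighted by $\lambda_\mathrm{cell}$ and
$\lambda_\mathrm{gene}$). A conditional latent-diffusion decoder
synthesizes cell images from $z_i$ under classifier-free guidance
$\tilde\epsilon = \epsilon_u + w(\epsilon_c - \epsilon_u)$, optionally
after gene perturbations (knockout / overexpression), and accelerates
sampling by merging low-importance attention tokens, where importance is
the per-token guidance magnitude $|\epsilon_c - \epsilon_u|$.

Everything is verifiable offline: a synthetic slide generator produces
segmented slides whose cell morphology is a known, invertible function of
type-level gene expression, giving every downstream claim a ground truth.

## Worked example

```r
library(stweave)

cfg <- synthetic_config(n_cell_types = 3L, n_genes = 30L,
                        slide_height = 384L, slide_width = 384L,
                        n_cells = 120L, seed = 7L)
slide_dir <- file.path(tempdir(), "slide")
simulate_slide(cfg, dir = slide_dir)
built <- build_dataset(slide_dir, file.path(tempdir(), "dataset"),
                       tile = 128L, tissue_tile = 384L)

model <- stw_model_new(stw_config(embed_dim = 32L, depth = 1L, n_genes = 30L,
                                  cell_input_px = 32L, niche_input_px = 32L,
                                  recon_px = 16L, seed = 1L))
fit <- stw_train(model, built, steps = 60L, batch_size = 8L, seed = 2L)
emb <- embed_dataset(built, model)

labels <- read.csv(file.path(slide_dir, "cells.csv"))$type_label
genes  <- do.call(rbind, lapply(built$cells, `[[`, "gene"))
cross_modal_fit(emb$zc, genes, "z2g", seed = 3L)$pearson
cluster_metrics(emb$zc, labels, seed = 4L)
```

Output:

```
cells: 120  niches: 9  tissues: 1
total loss: 3.957 -> 1.499
cross-modal Pearson: 0.61  ARI: 0.22  NMI: 0.26
```

The slide holds 120 cells in 9 occupied 128-px niches. Sixty
self-supervised steps cut the weighted reconstruction loss from 3.96 to
1.50. Even this toy run transfers information across modalities: a
perceptron reads expression back out of the image-fused embeddings at a
mean per-gene Pearson of 0.61, and k-means on whitened embedding PCs
begins to recover the generator's three cell types (ARI 0.22; the shipped
test suite trains a larger model on 2,000 cells, where types separate far
more cleanly). A command-line interface wraps the same stages:

```sh
Rscript inst/cli/stweave.R simulate --data.n_cells=500 --out run1
Rscript inst/cli/stweave.R build    --out run1
Rscript inst/cli/stweave.R train    --out run1
Rscript inst/cli/stweave.R embed    --out run1
Rscript inst/cli/stweave.R evaluate --out run1
Rscript inst/cli/stweave.R generate --out run1 --cell cell_00003 \
    --edit gene_0002:knockout --steps 25 --cfg 3.0 --merge-ratio 0.5
```

See `vignettes/stweave-methods.Rmd` for the model, its assumptions, and
every numerical design choice.

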