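# Modality- and scale-specific encoders.
#
# Images are encoded by small vision transformers (patch projection, learnable
# [CLS] token, learned positional embeddings, pre-norm self-attention blocks).
# Gene vectors are encoded per gene: a learnable gene-specific embedding is
# modulated (scaled) by log1p expression and shifted by a small MLP of the
# expression value, so the gene token matrix is local in the genes — changing
# one gene's count changes only that gene's token.

#' Encoder configuration
#'
#' @param embed_dim shared embedding width D (divisible by \code{n_heads}).
#' @param patch_px patch side in pixels (must divide \code{input_px}).
#' @param depth number of transformer blocks.
#' @param n_heads attention heads.
#' @param input_px model input image side in pixels.
#' @param dropout kept for interface compatibility; this implementation is
#'   deterministic (dropout 0).
#' @param seed seed used when the encoder's parameters are created.
#' @return an \code{encoder_config} list.
#' @export
encoder_config <- function(embed_dim = 64L, patch_px = 8L, depth = 2L,
                           n_heads = 4L, input_px = 64L, dropout = 0,
                           seed = 1L) {
  stopifnot(input_px %% patch_px == 0L, embed_dim %% n_heads == 0L)
  structure(list(embed_dim = as.integer(embed_dim),
                 patch_px = as.integer(patch_px), depth = as.integer(depth),
                 n_heads = as.integer(n_heads), input_px = as.integer(input_px),
                 dropout = dropout, seed = as.integer(seed)),
            class = "encoder_config")
}

#' @noRd
vit_new <- function(cfg) {
  d <- cfg$embed_dim
  side <- cfg$input_px %/% cfg$patch_px
  n <- side * side
  list(cfg = cfg,
       proj = linear_new(cfg$patch_px^2, d),
       cls = ag_param(rmat(1L, d, sd = 0.02)),
       pos = ag_param(rmat(n + 1L, d, sd = 0.02)),
       blocks = lapply(seq_len(cfg$depth), function(i) block_new(d, cfg$n_heads)),
       grid = c(side, side))
}

# Scale image pixel values to [0, 1] whatever the input convention.
#' @noRd
img01 <- function(img) {
  if (max(img) > 1) img / 255 else img + 0
}

# Cut an image into the row-major patch matrix (n_patches x patch_px^2).
#' @noRd
patch_matrix <- function(img, patch_px) {
  H <- nrow(img)
  gr <- H %/% patch_px
  a <- array(img, c(patch_px, gr, patch_px, gr))
  a <- aperm(a, c(4L, 2L, 1L, 3L)) # (gcol, grow, pi, pj)
  matrix(a, gr * gr, patch_px^2)
}

#' @noRd
fwd_patchify <- function(vit, img) {
  cfg <- vit$cfg
  if (nrow(img) != cfg$input_px || ncol(img) != cfg$input_px) {
    stop("image size ", nrow(img), "x", ncol(img),
         " does not match encoder input_px ", cfg$input_px)
  }
  pm <- patch_matrix(img01(img), cfg$patch_px)
  x <- linear_fwd(vit$proj, pm)
  x <- ag_rbind(list(vit$cls, x))
  ag_add(x, vit$pos)
}

#' @noRd
fwd_vit <- function(vit, img) {
  x <- fwd_patchify(vit, img)
  for (blk in vit$blocks) x <- block_fwd(blk, x)
  x
}

#' @noRd
token_sequence <- function(tokens, has_cls, grid_shape) {
  list(tokens = tokens, has_cls = has_cls, grid_shape = grid_shape)
}

#' Patchify an image into a pre-transformer token sequence
#'
#' Non-overlapping patches are flattened, linearly projected to D, prepended
#' with the learnable [CLS] token, and given learned positional embeddings.
#'
#' @param image square matrix whose side equals the encoder's
#'   \code{input_px}.
#' @param encoder a ViT encoder (e.g. \code{model$cell_enc}).
#' @return a token sequence: list with \code{tokens}
#'   ((n_patches + 1) x D), \code{has_cls = TRUE}, \code{grid_shape}.
#' @export
patchify <- function(image, encoder) {
  token_sequence(vv(fwd_patchify(encoder, image)), TRUE, encoder$grid)
}

#' Encode a cell crop into image tokens
#'
#' The crop is bilinearly resized to the encoder input size, patchified and
#' passed through the transformer blocks.
#'
#' @param crop square image matrix (any side).
#' @param model a model from \code{\link{stw_model_new}}.
#' @return a token sequence with CLS at row 1.
#' @export
encode_cell_image <- function(crop, model) {
  img <- resize_bilinear(img01(crop), model$config$cell_input_px)
  token_sequence(vv(fwd_vit(model$cell_enc, img)), TRUE, model$cell_enc$grid)
}

#' Encode a niche tile into image tokens
#'
#' @param niche_image tile image matrix (downsampled to the niche encoder
#'   input size internally).
#' @param model a model from \code{\link{stw_model_new}}.
#' @return a token sequence with CLS at row 1.
#' @export
encode_niche_image <- function(niche_image, model) {
  img <- resize_bilinear(img01(niche_image), model$config$niche_input_px)
  token_sequence(vv(fwd_vit(model$niche_enc, img)), TRUE, model$niche_enc$grid)
}

#' @noRd
gene_encoder_new <- function(n_genes, d, hidden = 16L) {
  list(emb = ag_param(rmat(n_genes, d, sd = 0.05)),
       fc1 = linear_new(1L, hidden), fc2 = linear_new(hidden, d))
}

#' @noRd
fwd_encode_genes <- function(model, g) {
  ge <- model$gene_enc
  s <- log1p(g)
  d <- ncol(ge$emb$v)
  mod <- ag_mul(ge$emb, matrix(s, length(s), d))
  shift <- linear_fwd(ge$fc2, ag_gelu(linear_fwd(ge$fc1, matrix(s, ncol = 1L))))
  ag_add(mod, shift)
}

#' Encode a gene expression vector into per-gene tokens
#'
#' Token j equals \code{gene_embedding_j * log1p(g_j) +
#' expression_mlp(log1p(g_j))}; a gene with zero count contributes only the
#' \code{expression_mlp(0)} term. The gene backbone is pluggable: pass any
#' \code{backbone} callable mapping a count vector to an N_gene x D matrix to
#' replace the built-in encoder.
#'
#' @param g nonnegative finite count/expression vector of length
#'   \code{model$config$n_genes}.
#' @param model a model from \code{\link{stw_model_new}}.
#' @param backbone optional replacement encoder callable.
#' @return list with \code{tokens} (N_gene x D), \code{gene_ids}, and
#'   \code{pooled} (row mean, length D).
#' @export
encode_genes <- function(g, model, backbone = NULL) {
  if (any(!is.finite(g)) || any(g < 0)) {
    stop("gene vector must be finite and nonnegative")
  }
  stopifnot(length(g) == model$config$n_genes)
  tokens <- if (is.null(backbone)) vv(fwd_encode_genes(model, g)) else backbone(g)
  list(tokens = tokens, gene_ids = model$config$gene_ids,
       pooled = colMeans(tokens))
}

#' @noRd
fwd_encode_tissue_tokens <- function(model, niche_embeddings, grid_positions) {
  d <- model$config$embed_dim
  pe <- sinusoidal_2d(grid_positions, d)
  x <- ag_add(niche_embeddings, pe)
  for (blk in model$tissue_blocks) x <- block_fwd(blk, x)
  x
}

#' Encode niche embeddings into a tissue token sequence
#'
#' Input tokens are the niche embeddings plus fixed 2-D sinusoidal positional
#' embeddings at their grid coordinates, passed through transformer blocks.
#'
#' @param niche_embeddings P x D matrix of niche-level embeddings.
#' @param grid_positions P x 2 integer matrix of (row, col) grid coordinates.
#' @param model a model from \code{\link{stw_model_new}}.
#' @return a token sequence without CLS (one token per niche).
#' @export
encode_tissue_tokens <- function(niche_embeddings, grid_positions, model) {
  stopifnot(ncol(niche_embeddings) == model$config$embed_dim,
            nrow(grid_positions) == nrow(niche_embeddings))
  token_sequence(vv(fwd_encode_tissue_tokens(model, niche_embeddings,
                                             grid_positions)),
                 FALSE, NA)
}

#' Model configuration (all scales)
#'
#' @param embed_dim shared width D.
#' @param n_heads attention heads.
#' @param depth transformer depth per encoder.
#' @param cell_input_px,cell_patch_px cell image encoder geometry.
#' @param niche_input_px,niche_patch_px niche image encoder geometry (niche
#'   tiles are downsampled to \code{niche_input_px}).
#' @param n_genes gene panel size G.
#' @param gene_ids optional gene identifiers (generated when NULL).
#' @param recon_px side of the image-reconstruction target.
#' @param mask_rate fraction of genes masked by the gene-reconstruction
#'   objective.
#' @param lambda_cell,lambda_gene loss weights (not both zero).
#' @param seed parameter initialization seed.
#' @return a \code{stw_config} list.
#' @export
stw_config <- function(embed_dim = 64L, n_heads = 4L, depth = 2L,
                       cell_input_px = 64L, cell_patch_px = 8L,
                       niche_input_px = 64L, niche_patch_px = 8L,
                       n_genes = 50L, gene_ids = NULL,
                       recon_px = 32L, mask_rate = 0.15,
                       lambda_cell = 1, lambda_gene = 1,
                       seed = 1L) {
  stopifnot(lambda_cell >= 0, lambda_gene >= 0, lambda_cell + lambda_gene > 0,
            mask_rate > 0, mask_rate < 1)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  structure(list(embed_dim = as.integer(embed_dim), n_heads = as.integer(n_heads),
                 depth = as.integer(depth),
                 cell_input_px = as.integer(cell_input_px),
                 cell_patch_px = as.integer(cell_patch_px),
                 niche_input_px = as.integer(niche_input_px),
                 niche_patch_px = as.integer(niche_patch_px),
                 n_genes = as.integer(n_genes), gene_ids = gene_ids,
                 recon_px = as.integer(recon_px), mask_rate = mask_rate,
                 lambda_cell = lambda_cell, lambda_gene = lambda_gene,
                 seed = as.integer(seed)),
            class = "stw_config")
}

#' Construct the full multi-scale model
#'
#' Builds the cell/niche image encoders, the gene encoder, the tissue
#' transformer, the four cross-attention fusion blocks, and the two
#' self-supervised decoders (pixel reconstruction and masked-gene
#' regression), all seeded from \code{config$seed}.
#'
#' @param config a \code{\link{stw_config}}.
#' @return a model object (nested list of parameter nodes).
#' @export
stw_model_new <- function(config) {
  stopifnot(inherits(config, "stw_config"))
  d <- config$embed_dim
  with_seed(config$seed, {
    model <- list(
      config = config,
      cell_enc = vit_new(encoder_config(d, config$cell_patch_px, config$depth,
                                        config$n_heads, config$cell_input_px,
                                        seed = config$seed)),
      gene_enc = gene_encoder_new(config$n_genes, d),
      niche_enc = vit_new(encoder_config(d, config$niche_patch_px, config$depth,
                                         config$n_heads, config$niche_input_px,
                                         seed = config$seed)),
      tissue_blocks = lapply(seq_len(config$depth),
                             function(i) block_new(d, config$n_heads)),
      fuse = list(cell = xblock_new(d, config$n_heads),
                  niche = xblock_new(d, config$n_heads),
                  tissue = xblock_new(d, config$n_heads),
                  unified = xblock_new(d, config$n_heads)),
      img_dec = img_decoder_new(d, config$recon_px),
      gene_dec = list(queries = ag_param(rmat(config$n_genes, d, sd = 0.05)),
                      ln = layernorm_new(d),
                      attn = mha_new(d, config$n_heads),
                      headW = ag_param(rmat(config$n_genes, d, sd = 0.1)),
                      headb = ag_param(numeric(config$n_genes)))
    )
    class(model) <- "stw_model"
    model
  })
}

# Image decoder: linear token expansion from z to a coarse channel grid,
# then transposed-conv upsampling to recon_px x recon_px.
#' @noRd
img_decoder_new <- function(d, recon_px) {
  base <- recon_px %/% 4L
  ch <- 8L
  list(base = base, ch = ch,
       fc = linear_new(d, base * base * ch),
       ct1 = list(W = ag_param(array(stats::rnorm(4 * 4 * ch * ch, sd = 0.05),
                                     c(4L, 4L, ch, ch))),
                  b = ag_param(numeric(ch))),
       ct2 = list(W = ag_param(array(stats::rnorm(4 * 4 * ch, sd = 0.05),
                                     c(4L, 4L, ch, 1L))),
                  b = ag_param(numeric(1L))))
}

#' @noRd
fwd_img_decode <- function(model, z) {
  dec <- model$img_dec
  h <- linear_fwd(dec$fc, z)
  h <- ag_reshape(h, c(dec$base, dec$base, dec$ch, 1L))
  h <- ag_gelu(ag_convt2d(h, dec$ct1$W, dec$ct1$b, stride = 2L, pad = 1L))
  ag_sigmoid(ag_convt2d(h, dec$ct2$W, dec$ct2$b, stride = 2L, pad = 1L))
}

#' Snapshot all parameter values of a model (checkpointing)
#' @param model a model object.
#' @return list of parameter arrays in a stable order.
#' @export
stw_state_dict <- function(model) {
  lapply(collect_params(model), function(p) p$v)
}

#' Restore parameter values saved by \code{\link{stw_state_dict}}
#' @param model a model object with matching architecture.
#' @param state list of parameter arrays.
#' @return the model, invisibly (parameters are updated in place).
#' @export
stw_load_state <- function(model, state) {
  params <- collect_params(model)
  stopifnot(length(params) == length(state))
  for (i in seq_along(params)) params[[i]]$v <- state[[i]]
  invisible(model)
}
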