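# Cross-attention fusion across modalities and scales.
#
# Cell level: image patch tokens query the gene token matrix (K = V = gene
# tokens); the fused CLS row is the cell embedding z^c. Niche level: the mean
# of member cell embeddings queries the niche image tokens. Tissue level: the
# niche embedding queries the tissue token sequence. The unified embedding
# attends from z^c over the stacked (z^c, z^n, z^t).

#' @noRd
scale_embedding <- function(vector, level, source_id = NULL) {
  structure(list(vector = as.numeric(vector), level = level,
                 source_id = source_id),
            class = "scale_embedding")
}

#' Create a standalone cross-attention parameter set
#'
#' @param embed_dim width D.
#' @param n_heads number of heads (divides D).
#' @param seed initialization seed.
#' @return parameter list (query/key/value/output projections).
#' @export
cross_attn_params <- function(embed_dim, n_heads, seed = 1L) {
  with_seed(seed, mha_new(embed_dim, n_heads))
}

#' Multi-head scaled dot-product cross-attention
#'
#' Standard attention: queries and keys are projected, per-head softmax over
#' keys (each weight row sums to 1), values aggregated and output-projected.
#'
#' @param Q n_q x D query matrix.
#' @param K,V n_k x D key and value matrices (n_k >= 1).
#' @param params from \code{\link{cross_attn_params}}.
#' @return list with \code{output} (n_q x D) and \code{weights} (list of
#'   per-head n_q x n_k attention weight matrices).
#' @export
cross_attention <- function(Q, K, V, params) {
  stopifnot(ncol(Q) == params$d, ncol(K) == params$d, ncol(V) == params$d,
            nrow(K) >= 1L, nrow(K) == nrow(V))
  res <- mha_fwd(params, Q, K, V)
  list(output = vv(res$out), weights = lapply(res$weights, vv))
}

#' @noRd
fwd_fuse_cell <- function(model, cell_tokens, gene_tokens) {
  y <- xblock_fwd(model$fuse$cell, cell_tokens, gene_tokens)
  ag_rows(y, 1L)
}

#' Fuse cell image tokens with gene tokens into a cell embedding
#'
#' Cross-attention with the image token sequence as queries and the gene
#' token matrix as keys and values (plus residual and feed-forward); the
#' embedding is read from the fused CLS row.
#'
#' @param Xc token sequence from \code{\link{encode_cell_image}} (must carry
#'   a CLS token).
#' @param Xg gene token matrix from \code{\link{encode_genes}}.
#' @param model a model object.
#' @param source_id optional id recorded on the embedding.
#' @return a cell-level \code{scale_embedding} (length-D vector).
#' @export
fuse_cell <- function(Xc, Xg, model, source_id = NULL) {
  if (!isTRUE(Xc$has_cls)) stop("cell token sequence lacks a CLS token")
  z <- vv(fwd_fuse_cell(model, Xc$tokens, Xg$tokens))
  scale_embedding(z, "cell", source_id)
}

#' Pool member-cell embeddings into a niche context vector
#'
#' @param cell_embeddings matrix with one member embedding per row, or a
#'   list of cell-level \code{scale_embedding}s (>= 1 member).
#' @return length-D arithmetic mean vector.
#' @export
pool_niche_context <- function(cell_embeddings) {
  if (is.list(cell_embeddings) && !is.matrix(cell_embeddings)) {
    cell_embeddings <- do.call(rbind, lapply(cell_embeddings, `[[`, "vector"))
  }
  if (is.null(nrow(cell_embeddings)) || nrow(cell_embeddings) < 1L) {
    stop("empty niche: no member embeddings to pool")
  }
  colMeans(cell_embeddings)
}

#' @noRd
fwd_fuse_niche <- function(model, zbar, niche_tokens) {
  xblock_fwd(model$fuse$niche, zbar, niche_tokens)
}

#' Fuse pooled cell context with niche image tokens
#'
#' Single-query cross-attention: the pooled member context is the query, the
#' niche image tokens are keys and values.
#'
#' @param zbar length-D pooled context from \code{\link{pool_niche_context}}.
#' @param Xn token sequence from \code{\link{encode_niche_image}}.
#' @param model a model object.
#' @param source_id optional id.
#' @return a niche-level \code{scale_embedding}.
#' @export
fuse_niche <- function(zbar, Xn, model, source_id = NULL) {
  z <- vv(fwd_fuse_niche(model, matrix(zbar, 1L), Xn$tokens))
  scale_embedding(z, "niche", source_id)
}

#' @noRd
fwd_fuse_tissue <- function(model, zn, tissue_tokens) {
  xblock_fwd(model$fuse$tissue, zn, tissue_tokens)
}

#' Fuse a niche embedding with the tissue token sequence
#'
#' @param zn length-D niche embedding (vector or niche
#'   \code{scale_embedding}).
#' @param Xt tissue token sequence from
#'   \code{\link{encode_tissue_tokens}}.
#' @param model a model object.
#' @param source_id optional id.
#' @return a tissue-level \code{scale_embedding}.
#' @export
fuse_tissue <- function(zn, Xt, model, source_id = NULL) {
  if (inherits(zn, "scale_embedding")) zn <- zn$vector
  z <- vv(fwd_fuse_tissue(model, matrix(zn, 1L), Xt$tokens))
  scale_embedding(z, "tissue", source_id)
}

#' @noRd
fwd_fuse_unified <- function(model, zc, zn = NULL, zt = NULL) {
  keys <- list(zc)
  if (!is.null(zn)) keys <- c(keys, list(zn))
  if (!is.null(zt)) keys <- c(keys, list(zt))
  kv <- if (length(keys) > 1L) ag_rbind(keys) else keys[[1]]
  xblock_fwd(model$fuse$unified, zc, kv)
}

#' Fuse the three scale embeddings into the unified cell embedding
#'
#' One cross-attention block with the cell embedding as the sole query over
#' the stacked cell/niche/tissue embeddings. Missing niche or tissue levels
#' fall back to attention over the remaining keys.
#'
#' @param zc cell embedding (vector or \code{scale_embedding}).
#' @param zn,zt optional niche and tissue embeddings.
#' @param model a model object.
#' @param source_id optional id.
#' @return a unified \code{scale_embedding} of length D.
#' @export
fuse_unified <- function(zc, zn = NULL, zt = NULL, model, source_id = NULL) {
  getv <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "scale_embedding")) x <- x$vector
    matrix(x, 1L)
  }
  z <- vv(fwd_fuse_unified(model, getv(zc), getv(zn), getv(zt)))
  scale_embedding(z, "unified", source_id)
}

# ---- whole-dataset embedding (evaluation mode) -------------------------------

# Forward-compute z^c for one prepared cell input (resized [0,1] crop).
#' @noRd
fwd_cell_embed <- function(model, crop_in, gene) {
  tok <- fwd_vit(model$cell_enc, crop_in)
  gtok <- fwd_encode_genes(model, gene)
  fwd_fuse_cell(model, tok, gtok)
}

#' Embed every cell of a built dataset at all scales
#'
#' Runs the full hierarchy in evaluation mode: per-cell fused embeddings,
#' pooled niche contexts fused with niche imagery, the tissue transformer
#' over niche embeddings, and the unified per-cell embedding.
#'
#' @param built output of \code{\link{build_dataset}} (or a list with
#'   \code{cells}, \code{niches}, \code{tissues} record lists).
#' @param model a model object.
#' @return list of matrices \code{zc}, \code{zn}, \code{zt} (per niche),
#'   \code{unified} (per cell), plus id vectors and the cell -> niche map.
#' @export
embed_dataset <- function(built, model) {
  cfg <- model$config
  cells <- built$cells
  niches <- built$niches
  tissues <- built$tissues
  n <- length(cells)
  d <- cfg$embed_dim
  cell_ids <- vapply(cells, `[[`, "", "cell_id")
  zc <- matrix(0, n, d, dimnames = list(cell_ids, NULL))
  crops_in <- lapply(cells, function(rec) {
    resize_bilinear(img01(rec$crop), cfg$cell_input_px)
  })
  for (i in seq_len(n)) {
    zc[i, ] <- vv(fwd_cell_embed(model, crops_in[[i]], cells[[i]]$gene))
  }
  nn <- length(niches)
  zn <- matrix(0, nn, d)
  niche_ids <- vapply(niches, `[[`, "", "niche_id")
  rownames(zn) <- niche_ids
  for (j in seq_len(nn)) {
    members <- match(niches[[j]]$member_cell_ids, cell_ids)
    zbar <- colMeans(zc[members, , drop = FALSE])
    ntok <- fwd_vit(model$niche_enc,
                    resize_bilinear(img01(niches[[j]]$image), cfg$niche_input_px))
    zn[j, ] <- vv(fwd_fuse_niche(model, matrix(zbar, 1L), vv(ntok)))
  }
  zt <- matrix(0, nn, d, dimnames = list(niche_ids, NULL))
  for (tis in tissues) {
    members <- match(tis$niche_ids, niche_ids)
    Xt <- fwd_encode_tissue_tokens(model, zn[members, , drop = FALSE],
                                   tis$niche_grid)
    for (j in members) {
      zt[j, ] <- vv(fwd_fuse_tissue(model, zn[j, , drop = FALSE], vv(Xt)))
    }
  }
  niche_of_cell <- integer(n)
  for (j in seq_len(nn)) {
    niche_of_cell[match(niches[[j]]$member_cell_ids, cell_ids)] <- j
  }
  unified <- matrix(0, n, d, dimnames = list(cell_ids, NULL))
  for (i in seq_len(n)) {
    j <- niche_of_cell[i]
    unified[i, ] <- vv(fwd_fuse_unified(model, zc[i, , drop = FALSE],
                                        zn[j, , drop = FALSE],
                                        zt[j, , drop = FALSE]))
  }
  list(zc = zc, zn = zn, zt = zt, unified = unified, cell_ids = cell_ids,
       niche_ids = niche_ids, niche_of_cell = niche_of_cell)
}
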