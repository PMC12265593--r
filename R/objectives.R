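# Self-supervised objectives: pixel reconstruction of the cell crop from the
# unified embedding, masked-gene regression through learnable gene queries,
# and the lambda-weighted total loss; plus the seeded training loop.

#' Loss weights
#' @param lambda_cell weight of the image reconstruction loss (>= 0).
#' @param lambda_gene weight of the masked-gene loss (>= 0); not both zero.
#' @return a \code{loss_weights} list.
#' @export
loss_weights <- function(lambda_cell = 1, lambda_gene = 1) {
  stopifnot(lambda_cell >= 0, lambda_gene >= 0, lambda_cell + lambda_gene > 0)
  structure(list(lambda_cell = lambda_cell, lambda_gene = lambda_gene),
            class = "loss_weights")
}

#' Seeded gene mask plan
#'
#' @param n_genes panel size G.
#' @param mask_rate fraction of genes to mask, in (0, 1).
#' @param seed integer seed.
#' @return list with logical \code{mask} (at least one TRUE),
#'   \code{mask_rate} and \code{seed}.
#' @export
mask_plan <- function(n_genes, mask_rate = 0.15, seed = 1L) {
  stopifnot(mask_rate > 0, mask_rate < 1, n_genes >= 1L)
  with_seed(seed, {
    k <- max(1L, round(mask_rate * n_genes))
    mask <- rep(FALSE, n_genes)
    mask[sample.int(n_genes, k)] <- TRUE
    list(mask = mask, mask_rate = mask_rate, seed = as.integer(seed))
  })
}

#' @noRd
fwd_image_recon_loss <- function(model, z, target) {
  chat <- fwd_img_decode(model, z)
  ag_mse(chat, array(target, dim(vv(chat))))
}

#' Image reconstruction loss
#'
#' Decodes the embedding to a \code{recon_px} image (linear token expansion
#' plus transposed-conv upsampling) and returns the mean squared pixel error
#' against the target crop on the \code{[0, 1]} scale (mean over all pixels).
#'
#' @param z unified embedding (\code{scale_embedding} or length-D vector).
#' @param C target crop (any square size; resized to the decoder's output
#'   size and scaled to \code{[0, 1]}).
#' @param model a model object.
#' @return nonnegative scalar.
#' @export
image_recon_loss <- function(z, C, model) {
  if (inherits(z, "scale_embedding")) z <- z$vector
  target <- resize_bilinear(img01(C), model$config$recon_px)
  as.numeric(vv(fwd_image_recon_loss(model, matrix(z, 1L), target)))
}

#' @noRd
fwd_gene_recon_loss <- function(model, z, g, plan) {
  dec <- model$gene_dec
  mem <- ln_fwd(dec$ln, z)
  h <- ag_add(dec$queries, mha_fwd(dec$attn, dec$queries, mem, mem)$out)
  pred <- ag_add(ag_rowsums(ag_mul(h, dec$headW)),
                 ag_reshape(dec$headb, c(length(vv(dec$headb)), 1L)))
  midx <- which(plan$mask)
  ag_mse(ag_rows(pred, midx), matrix(log1p(g[midx]), ncol = 1L))
}

#' Masked-gene reconstruction loss
#'
#' All gene query embeddings cross-attend to the unified embedding (a single
#' memory token); a per-gene linear head predicts log1p expression, and the
#' mean squared error is taken over the masked positions only.
#'
#' @param z unified embedding (\code{scale_embedding} or vector).
#' @param g target count vector (length G).
#' @param plan a \code{\link{mask_plan}}.
#' @param model a model object.
#' @return nonnegative scalar.
#' @export
gene_recon_loss <- function(z, g, plan, model) {
  if (inherits(z, "scale_embedding")) z <- z$vector
  if (!any(plan$mask)) stop("mask plan masks no genes")
  as.numeric(vv(fwd_gene_recon_loss(model, matrix(z, 1L), g, plan)))
}

#' Weighted total loss
#' @param img_loss,gene_loss nonnegative component losses.
#' @param w a \code{\link{loss_weights}}.
#' @return \code{lambda_cell * img_loss + lambda_gene * gene_loss}.
#' @export
total_loss <- function(img_loss, gene_loss, w) {
  w$lambda_cell * img_loss + w$lambda_gene * gene_loss
}

# Precompute per-cell training inputs (resized input crop, recon target).
#' @noRd
prep_training_cells <- function(model, cells) {
  cfg <- model$config
  lapply(cells, function(rec) {
    raw <- img01(rec$crop)
    list(crop_in = resize_bilinear(raw, cfg$cell_input_px),
         target = resize_bilinear(raw, cfg$recon_px),
         gene = rec$gene)
  })
}

# Niche/tissue context for every cell, evaluated without gradients
# (stop-gradient: a cell's loss never backpropagates through other cells).
#' @noRd
compute_context <- function(model, built) {
  emb <- embed_dataset(built, model)
  list(zn = emb$zn[emb$niche_of_cell, , drop = FALSE],
       zt = emb$zt[emb$niche_of_cell, , drop = FALSE])
}

#' Train the multi-scale model with the self-supervised objectives
#'
#' Seeded single-process loop over cell records. Niche and tissue context
#' embeddings are recomputed (without gradient) at every epoch boundary and
#' treated as constants inside a step. Each step samples a batch, runs the
#' fused forward pass per cell, applies the weighted dual-decoder loss and
#' an AdamW update. A loss component with zero weight is skipped entirely,
#' so its decoder parameters stay at initialization.
#'
#' @param model a model from \code{\link{stw_model_new}} (updated in place).
#' @param built dataset from \code{\link{build_dataset}}.
#' @param steps number of optimization steps.
#' @param batch_size cells per step.
#' @param lr AdamW learning rate.
#' @param weights a \code{\link{loss_weights}}.
#' @param seed seed controlling batch order and gene masks.
#' @param start_step first step index (use with \code{opt} to resume from a
#'   checkpoint; resuming at an epoch boundary, where the context is
#'   recomputed anyway, continues the trace bit-compatibly).
#' @param opt optimizer state from a previous call (NULL starts fresh).
#' @return list with the \code{model}, per-step loss \code{trace}
#'   (data.frame step/img/gene/total), and the optimizer state \code{opt}.
#' @export
stw_train <- function(model, built, steps = 200L, batch_size = 8L, lr = 1e-3,
                      weights = loss_weights(), seed = 1L,
                      start_step = 1L, opt = NULL) {
  cells <- built$cells
  n <- length(cells)
  if (n < 1L) stop("empty dataset")
  prep <- prep_training_cells(model, cells)
  params <- collect_params(model)
  if (is.null(opt)) opt <- opt_adamw(params, lr = lr)
  steps_per_epoch <- max(1L, ceiling(n / batch_size))
  ctx <- NULL
  trace <- vector("list", steps)
  use_img <- weights$lambda_cell > 0
  use_gene <- weights$lambda_gene > 0
  for (k in seq_len(steps)) {
    step <- start_step + k - 1L
    if (is.null(ctx) || (step - 1L) %% steps_per_epoch == 0L) {
      ctx <- compute_context(model, built)
    }
    idx <- with_seed(seed * 1000L + step, sample.int(n, min(batch_size, n)))
    zero_grads(params)
    img_l <- 0; gene_l <- 0
    for (b in seq_along(idx)) {
      i <- idx[b]
      plan <- mask_plan(model$config$n_genes, model$config$mask_rate,
                        seed = seed * 100000L + step * 100L + b)
      ag_tape_start()
      z <- local({
        zc <- fwd_cell_embed(model, prep[[i]]$crop_in, prep[[i]]$gene)
        fwd_fuse_unified(model, zc, ctx$zn[i, , drop = FALSE],
                         ctx$zt[i, , drop = FALSE])
      })
      li <- if (use_img) fwd_image_recon_loss(model, z, prep[[i]]$target) else NULL
      lg <- if (use_gene) fwd_gene_recon_loss(model, z, prep[[i]]$gene, plan) else NULL
      tot <- NULL
      if (!is.null(li)) tot <- ag_scale(li, weights$lambda_cell)
      if (!is.null(lg)) {
        lgw <- ag_scale(lg, weights$lambda_gene)
        tot <- if (is.null(tot)) lgw else ag_add(tot, lgw)
      }
      tot <- ag_scale(tot, 1 / length(idx))
      if (!is.finite(vv(tot))) {
        ag_tape_stop()
        stop("non-finite loss at step ", step)
      }
      ag_backward(tot)
      ag_tape_stop()
      img_l <- img_l + if (is.null(li)) 0 else vv(li) / length(idx)
      gene_l <- gene_l + if (is.null(lg)) 0 else vv(lg) / length(idx)
    }
    opt_step(opt)
    trace[[k]] <- data.frame(step = step, img = img_l, gene = gene_l,
                             total = total_loss(img_l, gene_l, weights))
  }
  list(model = model, trace = do.call(rbind, trace), opt = opt)
}

#' Save a training checkpoint
#' @param model a model object.
#' @param opt optimizer state from \code{\link{stw_train}} (optional).
#' @param path file path.
#' @return the path, invisibly.
#' @export
stw_checkpoint_save <- function(model, opt = NULL, path) {
  obj <- list(config = model$config, state = stw_state_dict(model))
  if (!is.null(opt)) obj$opt <- list(m = opt$m, u = opt$u, t = opt$t,
                                     lr = opt$lr, b1 = opt$b1, b2 = opt$b2,
                                     eps = opt$eps, wd = opt$wd)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a training checkpoint
#' @param path file written by \code{\link{stw_checkpoint_save}}.
#' @return list with restored \code{model} and (possibly NULL) \code{opt}.
#' @export
stw_checkpoint_load <- function(path) {
  obj <- readRDS(path)
  model <- stw_model_new(obj$config)
  stw_load_state(model, obj$state)
  opt <- NULL
  if (!is.null(obj$opt)) {
    opt <- opt_adamw(collect_params(model), lr = obj$opt$lr,
                     beta1 = obj$opt$b1, beta2 = obj$opt$b2,
                     eps = obj$opt$eps, weight_decay = obj$opt$wd)
    opt$m <- obj$opt$m
    opt$u <- obj$opt$u
    opt$t <- obj$opt$t
  }
  list(model = model, opt = opt)
}
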