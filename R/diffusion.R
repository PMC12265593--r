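# Conditional latent-diffusion decoder.
#
# A frozen convolutional autoencoder maps 64-px cell crops to 16x16x4 latents
# (downsampling factor 4). A lightweight 2-level U-Net denoises latents; at
# each resolution it applies a self-attention block (where token merging acts
# at sampling time) and a cross-attention block over a single conditioning
# token, the unified cell embedding. Sampling is deterministic DDIM with
# classifier-free guidance; per-token CFG importance selects anchor tokens
# and non-anchors are softly (non-exclusively) merged into them.

# ---- noise schedule ----------------------------------------------------------

#' Linear DDPM noise schedule
#'
#' A linear beta ramp referenced to 1000 steps and rescaled to \code{T}
#' steps, so the terminal signal level is comparable at reduced step counts.
#' \code{alpha_bar} is strictly decreasing and extends to
#' \code{alpha_bar[t = 0] = 1}.
#'
#' @param T number of diffusion steps.
#' @param beta_min,beta_max beta range at the 1000-step reference.
#' @param ref_T reference step count for the rescaling.
#' @return a \code{noise_schedule}: list with \code{T}, \code{betas},
#'   \code{alphas}, \code{alpha_bar}.
#' @export
noise_schedule <- function(T = 100L, beta_min = 1e-4, beta_max = 0.02,
                           ref_T = 1000L) {
  # keep every beta strictly inside (0, 1) at very small step counts
  scale <- min(ref_T / T, 0.98 / beta_max)
  betas <- seq(beta_min * scale, beta_max * scale, length.out = T)
  stopifnot(all(betas > 0), all(betas < 1))
  alphas <- 1 - betas
  abar <- cumprod(alphas)
  stopifnot(all(diff(abar) < 0), abar[1] > 0.9)
  structure(list(T = as.integer(T), betas = betas, alphas = alphas,
                 alpha_bar = abar), class = "noise_schedule")
}

#' @noRd
abar_at <- function(schedule, t) {
  if (t == 0L) 1 else schedule$alpha_bar[t]
}

#' Forward diffusion (closed form)
#'
#' \code{x_t = sqrt(alpha_bar_t) x0 + sqrt(1 - alpha_bar_t) noise}. \code{t
#' = 0} is the identity extension.
#'
#' @param x0 clean latent array.
#' @param t integer step in \code{0..T}.
#' @param noise array like \code{x0}.
#' @param schedule a \code{\link{noise_schedule}}.
#' @return the noised latent.
#' @export
q_sample <- function(x0, t, noise, schedule) {
  if (t < 0L || t > schedule$T) stop("t out of range [0, T]")
  ab <- abar_at(schedule, t)
  sqrt(ab) * x0 + sqrt(1 - ab) * noise
}

# ---- condition / guidance types ---------------------------------------------

#' Conditioning signal for the diffusion decoder
#' @param z_cond length-D unified embedding (ignored when \code{is_null}).
#' @param is_null TRUE selects the learned null (unconditional) token.
#' @return a \code{condition_signal}.
#' @export
condition_signal <- function(z_cond, is_null = FALSE) {
  if (!is_null) stopifnot(all(is.finite(z_cond)))
  structure(list(z_cond = as.numeric(z_cond), is_null = is_null),
            class = "condition_signal")
}

#' Classifier-free guidance configuration
#' @param w guidance weight (>= 0, finite). \code{w = 0} returns the
#'   unconditional prediction, \code{w = 1} the conditional one.
#' @return a \code{guidance_config}.
#' @export
guidance_config <- function(w = 3) {
  stopifnot(is.finite(w), w >= 0)
  structure(list(w = w), class = "guidance_config")
}

#' Combine conditional and unconditional noise predictions
#'
#' \code{eps_uncond + w * (eps_cond - eps_uncond)}, elementwise.
#'
#' @param eps_uncond,eps_cond same-shape arrays.
#' @param w guidance weight (numeric or \code{\link{guidance_config}}).
#' @return guided noise prediction.
#' @export
cfg_combine <- function(eps_uncond, eps_cond, w) {
  if (inherits(w, "guidance_config")) w <- w$w
  if (!identical(dim(eps_uncond), dim(eps_cond))) stop("shape mismatch")
  # the w = 0 / w = 1 endpoints return the branch itself exactly
  if (w == 0) return(eps_uncond)
  if (w == 1) return(eps_cond)
  eps_uncond + w * (eps_cond - eps_uncond)
}

# ---- CFG-importance token merging -------------------------------------------

#' Per-token CFG importance
#'
#' The absolute conditional/unconditional difference summed over channels,
#' average-pooled to \code{target_grid} and flattened row-major.
#'
#' @param eps_uncond,eps_cond latent noise predictions, (H, W, C) or
#'   (H, W, C, 1) arrays of equal shape.
#' @param target_grid c(rows, cols); must divide the latent grid.
#' @return list with nonnegative \code{scores} (length rows*cols) and
#'   \code{grid}.
#' @export
token_importance <- function(eps_uncond, eps_cond, target_grid = NULL) {
  if (!identical(dim(eps_uncond), dim(eps_cond))) stop("shape mismatch")
  d <- dim(eps_uncond)
  a <- abs(eps_cond - eps_uncond)
  if (length(d) == 4L) {
    a <- array(a, d[1:3])
    d <- d[1:3]
  }
  imp <- apply(a, c(1L, 2L), sum)
  if (is.null(target_grid)) target_grid <- dim(imp)
  fh <- nrow(imp) / target_grid[1]
  fw <- ncol(imp) / target_grid[2]
  if (fh != round(fh) || fw != round(fw)) stop("target_grid must divide the latent grid")
  if (fh > 1 || fw > 1) {
    pool <- matrix(0, target_grid[1], target_grid[2])
    for (i in seq_len(target_grid[1])) for (j in seq_len(target_grid[2])) {
      pool[i, j] <- mean(imp[((i - 1) * fh + 1):(i * fh),
                             ((j - 1) * fw + 1):(j * fw)])
    }
    imp <- pool
  }
  list(scores = as.vector(t(imp)), grid = target_grid)
}

#' Select anchor tokens from importance scores
#'
#' Keeps \code{M = max(1, ceiling((1 - r) * N))} indices of the largest
#' scores; ties are broken toward the lower index; the result is sorted.
#'
#' @param scores nonnegative importance vector (or output of
#'   \code{\link{token_importance}}).
#' @param r merge ratio in \code{[0, 1)}.
#' @return sorted integer anchor indices.
#' @export
select_anchors <- function(scores, r) {
  if (is.list(scores)) scores <- scores$scores
  n <- length(scores)
  if (n < 1L) stop("empty scores")
  stopifnot(r >= 0, r < 1)
  m <- max(1L, as.integer(ceiling((1 - r) * n)))
  sort(order(-scores, seq_len(n))[seq_len(m)])
}

#' Build a non-exclusive soft merge plan
#'
#' Each non-anchor token is softly assigned to every anchor with weights
#' \code{softmax_k(q_j . k_k / sqrt(d_head))}, logits averaged over heads;
#' rows sum to 1 and a token may weight several anchors.
#'
#' @param queries,keys N x d matrices (the attention module's projections).
#' @param anchors anchor index vector (subset of 1..N).
#' @param n_heads heads used for the head-averaged logits.
#' @return a \code{merge_plan}: \code{anchor_indices},
#'   \code{non_anchor_indices}, \code{assignment} ((N-M) x M, rows sum to
#'   1), \code{n_tokens}.
#' @export
build_merge_plan <- function(queries, keys, anchors, n_heads = 1L) {
  n <- nrow(queries)
  if (length(anchors) < 1L) stop("anchor set empty")
  stopifnot(all(anchors >= 1L), all(anchors <= n), !anyDuplicated(anchors))
  anchors <- sort(anchors)
  non <- setdiff(seq_len(n), anchors)
  d <- ncol(queries)
  dh <- d %/% n_heads
  logits <- matrix(0, length(non), length(anchors))
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    logits <- logits + queries[non, cols, drop = FALSE] %*%
      t(keys[anchors, cols, drop = FALSE]) / sqrt(dh)
  }
  logits <- logits / n_heads
  if (length(non) > 0L) {
    logits <- logits - apply(logits, 1L, max)
    e <- exp(logits)
    A <- e / rowSums(e)
  } else {
    A <- matrix(0, 0L, length(anchors))
  }
  structure(list(anchor_indices = anchors, non_anchor_indices = non,
                 assignment = A, n_tokens = n),
            class = "merge_plan")
}

#' Merge tokens into anchors by weighted averaging
#'
#' \code{merged_k = (token_k + sum_j a_jk token_j) / (1 + sum_j a_jk)}.
#'
#' @param tokens N x d matrix.
#' @param plan a \code{\link{build_merge_plan}} result.
#' @return M x d merged token matrix.
#' @export
merge_tokens <- function(tokens, plan) {
  stopifnot(nrow(tokens) == plan$n_tokens)
  anc <- tokens[plan$anchor_indices, , drop = FALSE]
  if (length(plan$non_anchor_indices) == 0L) return(anc)
  A <- plan$assignment
  num <- anc + t(A) %*% tokens[plan$non_anchor_indices, , drop = FALSE]
  num / (1 + colSums(A))
}

#' Redistribute merged attention outputs to the full token sequence
#'
#' Anchor rows are copied back; non-anchor row j is its assignment-weighted
#' combination of the merged outputs.
#'
#' @param merged_out M x d matrix (attention output on the merged tokens).
#' @param plan the plan used for merging.
#' @return N x d matrix.
#' @export
unmerge_outputs <- function(merged_out, plan) {
  stopifnot(nrow(merged_out) == length(plan$anchor_indices))
  out <- matrix(0, plan$n_tokens, ncol(merged_out))
  out[plan$anchor_indices, ] <- merged_out
  if (length(plan$non_anchor_indices) > 0L) {
    out[plan$non_anchor_indices, ] <- plan$assignment %*% merged_out
  }
  out
}

# ---- VAE ---------------------------------------------------------------------

#' @noRd
conv_new <- function(k, cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (k * k * cin + cout))
  list(W = ag_param(array(stats::rnorm(k * k * cin * cout, sd = sd),
                          c(k, k, cin, cout))),
       b = ag_param(numeric(cout)))
}

#' Create the convolutional autoencoder for the latent space
#'
#' Encoder downsamples by factor 4 to a \code{latent_ch}-channel latent;
#' decoding is deterministic (mean decode, no sampling). Train with
#' \code{\link{vae_train}}, then freeze before diffusion training.
#'
#' @param latent_ch latent channels (default 4).
#' @param base_ch first conv width.
#' @param seed init seed.
#' @return a \code{stw_vae}.
#' @export
vae_new <- function(latent_ch = 4L, base_ch = 8L, seed = 1L) {
  with_seed(seed, {
    v <- list(latent_ch = latent_ch, f = 4L, frozen = FALSE,
              e1 = conv_new(4L, 1L, base_ch),
              e2 = conv_new(4L, base_ch, 2L * base_ch),
              e3 = conv_new(3L, 2L * base_ch, latent_ch),
              d1 = conv_new(3L, latent_ch, 2L * base_ch),
              d2 = conv_new(4L, 2L * base_ch, base_ch),   # convT 2b -> b
              d3 = conv_new(4L, base_ch, 1L))             # convT b -> 1
    class(v) <- "stw_vae"
    v
  })
}

#' @noRd
fwd_vae_encode <- function(vae, x) {
  h <- ag_gelu(ag_conv2d(x, vae$e1$W, vae$e1$b, stride = 2L, pad = 1L))
  h <- ag_gelu(ag_conv2d(h, vae$e2$W, vae$e2$b, stride = 2L, pad = 1L))
  ag_conv2d(h, vae$e3$W, vae$e3$b, stride = 1L, pad = 1L)
}

#' @noRd
fwd_vae_decode <- function(vae, z) {
  h <- ag_gelu(ag_conv2d(z, vae$d1$W, vae$d1$b, stride = 1L, pad = 1L))
  h <- ag_gelu(ag_convt2d(h, vae$d2$W, vae$d2$b, stride = 2L, pad = 1L))
  ag_sigmoid(ag_convt2d(h, vae$d3$W, vae$d3$b, stride = 2L, pad = 1L))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode images to latents (deterministic)
#' @param vae a trained \code{stw_vae}.
#' @param images (H, W, 1, B) array, or a single H x W matrix, on [0, 1].
#' @return (H/4, W/4, latent_ch, B) latent array.
#' @export
vae_encode <- function(vae, images) {
  if (is.matrix(images)) {
    images <- array(images, c(nrow(images), ncol(images), 1L, 1L))
  }
  vv(fwd_vae_encode(vae, images))
}

#' Decode latents to images (deterministic mean decode)
#' @param vae a trained \code{stw_vae}.
#' @param latents (h, w, latent_ch, B) array.
#' @return (H, W, 1, B) array on [0, 1].
#' @export
vae_decode <- function(vae, latents) {
  vv(fwd_vae_decode(vae, latents))
}

#' Train the autoencoder on cell crops (stage 0)
#'
#' Pixel MSE reconstruction with AdamW; the returned model is frozen and is
#' the fixed pixel/latent mapping of the diffusion decoder.
#'
#' @param vae from \code{\link{vae_new}}.
#' @param crops list of square image matrices (scaled internally to [0,1]).
#' @param steps,batch_size,lr optimization settings.
#' @param seed seed for batch order.
#' @return list with frozen \code{vae} and loss \code{trace}.
#' @export
vae_train <- function(vae, crops, steps = 300L, batch_size = 8L, lr = 2e-3,
                      seed = 1L) {
  xs <- lapply(crops, img01)
  n <- length(xs)
  params <- collect_params(vae[c("e1", "e2", "e3", "d1", "d2", "d3")])
  opt <- opt_adamw(params, lr = lr)
  trace <- numeric(steps)
  for (s in seq_len(steps)) {
    idx <- with_seed(seed * 1000L + s, sample.int(n, min(batch_size, n)))
    xb <- array(0, c(nrow(xs[[1]]), ncol(xs[[1]]), 1L, length(idx)))
    for (b in seq_along(idx)) xb[, , 1L, b] <- xs[[idx[b]]]
    zero_grads(params)
    ag_tape_start()
    rec <- fwd_vae_decode(vae, fwd_vae_encode(vae, xb))
    loss <- ag_mse(rec, xb)
    trace[s] <- vv(loss)
    if (!is.finite(trace[s])) { ag_tape_stop(); stop("non-finite VAE loss") }
    ag_backward(loss)
    ag_tape_stop()
    opt_step(opt)
  }
  vae$frozen <- TRUE
  list(vae = vae, trace = trace)
}

# ---- U-Net denoiser ----------------------------------------------------------

#' @noRd
unet_attn_new <- function(ch, n_heads, d_cond) {
  list(ln1 = layernorm_new(ch), attn = mha_new(ch, n_heads),
       ln2 = layernorm_new(ch), xattn = mha_new(ch, n_heads),
       cond_proj = linear_new(d_cond, ch))
}

# Self-attention (optionally token-merged) + cross-attention over the single
# conditioning token, applied per batch element on an (H,W,C,B) map.
#' @noRd
unet_attn_fwd <- function(blk, x, cond, merge = NULL, telemetry = NULL) {
  d <- dim(vv(x))
  H <- d[1]; W <- d[2]; B <- d[4]
  cond_tok <- linear_fwd(blk$cond_proj, cond) # B x ch
  parts <- vector("list", B)
  for (b in seq_len(B)) {
    tok <- ag_tokens_from_map(ag_slice_b(x, b))
    tn <- ln_fwd(blk$ln1, tok)
    if (is.null(merge)) {
      sa <- mha_fwd(blk$attn, tn, tn, tn)$out
    } else {
      sa <- merged_self_attention(blk$attn, vv(tn), merge$scores[[b]], merge$r,
                                  telemetry = telemetry)
    }
    tok <- ag_add(tok, sa)
    kv <- ag_rows(cond_tok, b)
    tok <- ag_add(tok, mha_fwd(blk$xattn, ln_fwd(blk$ln2, tok), kv, kv)$out)
    parts[[b]] <- ag_map_from_tokens(tok, H, W)
  }
  ag_stack_b(parts)
}

# Importance-guided merged self-attention on plain numeric tokens
# (inference only). With r = 0 this is byte-identical to dense attention.
#' @noRd
merged_self_attention <- function(p, tn, scores, r, telemetry = NULL) {
  if (r <= 0) {
    return(mha_fwd(p, tn, tn, tn)$out)
  }
  anchors <- select_anchors(scores, r)
  Q <- vv(linear_fwd(p$Wq, tn))
  K <- vv(linear_fwd(p$Wk, tn))
  plan <- build_merge_plan(Q, K, anchors, n_heads = p$n_heads)
  tm <- merge_tokens(tn, plan)
  out_m <- mha_fwd(p, tm, tm, tm)$out
  if (!is.null(telemetry)) {
    telemetry$log[[length(telemetry$log) + 1L]] <-
      list(tokens_before = nrow(tn), tokens_after = nrow(tm))
  }
  unmerge_outputs(vv(out_m), plan)
}

#' Create the lightweight denoising U-Net
#'
#' Two down / two up levels on 16x16 latents, with a self-attention and a
#' cross-attention block at each resolution; conditioning enters as a single
#' projected token of the unified embedding (a learned null token serves the
#' unconditional branch).
#'
#' @param d_cond conditioning width D.
#' @param ch base channels.
#' @param n_heads attention heads.
#' @param latent_ch latent channels.
#' @param seed init seed.
#' @return a \code{stw_unet}.
#' @export
unet_new <- function(d_cond, ch = 16L, n_heads = 4L, latent_ch = 4L,
                     seed = 1L) {
  with_seed(seed, {
    u <- list(d_cond = d_cond, ch = ch, temb_d = 32L,
              latent_ch = latent_ch,
              null_token = ag_param(rmat(1L, d_cond, sd = 0.02)),
              cond_ln = layernorm_new(d_cond),
              cond_mlp = linear_new(d_cond, 32L),
              cond_chproj = linear_new(d_cond, latent_ch),
              tproj1 = linear_new(32L, ch), tproj2 = linear_new(32L, 2L * ch),
              c_in = conv_new(3L, 2L * latent_ch, ch),
              attn16 = unet_attn_new(ch, n_heads, d_cond),
              c_down = conv_new(4L, ch, 2L * ch),
              attn8 = unet_attn_new(2L * ch, n_heads, d_cond),
              c_mid = conv_new(3L, 2L * ch, 2L * ch),
              c_up = conv_new(4L, 2L * ch, ch),   # convT: 2ch -> ch
              c_fuse = conv_new(3L, 2L * ch, ch),
              c_out = conv_new(3L, ch, latent_ch))
    class(u) <- "stw_unet"
    u
  })
}

# Full U-Net pass. x: (16,16,4,B); t: length-B integer steps; cond: B x
# d_cond (rows with null_mask TRUE are replaced by the learned null token).
# merge: NULL or list(r, scores16 = list per b, scores8 = list per b).
#' @noRd
unet_fwd <- function(u, x, t, cond, null_mask = NULL, schedule_T = 100L,
                     merge = NULL, telemetry = NULL) {
  B <- dim(vv(x))[4]
  if (is.null(null_mask)) null_mask <- rep(FALSE, B)
  crows <- vector("list", B)
  for (b in seq_len(B)) {
    crows[[b]] <- if (null_mask[b]) u$null_token
    else matrix(if (is.matrix(cond)) cond[b, ] else cond, 1L)
  }
  # normalize the conditioning token so its scale cannot swamp the network,
  # then inject it both as the cross-attention context and into the
  # timestep pathway (class-conditional FiLM-style biasing at every level)
  condm <- ln_fwd(u$cond_ln, ag_rbind(crows))
  temb <- ag_add(timestep_embedding(t / schedule_T, u$temb_d),
                 linear_fwd(u$cond_mlp, condm))
  t1 <- ag_t(linear_fwd(u$tproj1, temb)) # ch x B
  t2 <- ag_t(linear_fwd(u$tproj2, temb))
  # condition also enters as extra input channels (spatially broadcast), the
  # most direct conditioning path for the convolution stack
  d <- dim(vv(x))
  cch <- ag_add_chmat(array(0, d), ag_t(linear_fwd(u$cond_chproj, condm)))
  xin <- ag_concat_ch(x, cch)
  h1 <- ag_gelu(ag_add_chmat(ag_conv2d(xin, u$c_in$W, u$c_in$b, 1L, 1L), t1))
  m16 <- if (is.null(merge)) NULL else list(scores = merge$scores16, r = merge$r)
  h1 <- unet_attn_fwd(u$attn16, h1, condm, m16, telemetry)
  h2 <- ag_gelu(ag_add_chmat(ag_conv2d(h1, u$c_down$W, u$c_down$b, 2L, 1L), t2))
  m8 <- if (is.null(merge)) NULL else list(scores = merge$scores8, r = merge$r)
  h2 <- unet_attn_fwd(u$attn8, h2, condm, m8, telemetry)
  h2 <- ag_gelu(ag_conv2d(h2, u$c_mid$W, u$c_mid$b, 1L, 1L))
  up <- ag_gelu(ag_convt2d(h2, u$c_up$W, u$c_up$b, 2L, 1L))
  cat <- ag_concat_ch(up, h1)
  hf <- ag_gelu(ag_conv2d(cat, u$c_fuse$W, u$c_fuse$b, 1L, 1L))
  # input residual: at high noise the optimal prediction is close to the
  # identity on x_t, which the conv stack need not learn from scratch
  ag_add(ag_conv2d(hf, u$c_out$W, u$c_out$b, 1L, 1L), x)
}

#' Predict noise for a batch of latents
#'
#' The network is trained in the clean-latent (x0) parameterization — at
#' every noise level it regresses toward the condition's clean latent,
#' which keeps the conditioning signal first-order — and the noise
#' prediction is recovered algebraically as
#' \code{(x_t - sqrt(alpha_bar) x0_hat) / sqrt(1 - alpha_bar)}, so
#' guidance operates on noise predictions as usual.
#'
#' @param dd diffusion decoder from \code{\link{diffusion_new}}.
#' @param x_t (h, w, latent_ch, B) noised latents.
#' @param t integer step (scalar or length-B).
#' @param cond a \code{\link{condition_signal}} or B x D matrix; the null
#'   signal uses the learned unconditional token.
#' @return noise prediction with the shape of \code{x_t}.
#' @export
predict_noise <- function(dd, x_t, t, cond) {
  B <- dim(x_t)[4]
  if (length(t) == 1L) t <- rep(t, B)
  null_mask <- rep(FALSE, B)
  cm <- cond
  if (inherits(cond, "condition_signal")) {
    null_mask <- rep(cond$is_null, B)
    cm <- matrix(cond$z_cond, B, dd$unet$d_cond, byrow = TRUE)
    if (cond$is_null) cm <- matrix(0, B, dd$unet$d_cond)
  }
  x0h <- vv(unet_fwd(dd$unet, x_t, t, cm, null_mask, dd$schedule$T))
  eps_from_x0(dd$schedule, x_t, x0h, t)
}

# convert an x0 prediction into the equivalent noise prediction, per batch
# element
#' @noRd
eps_from_x0 <- function(schedule, x_t, x0h, t) {
  out <- 0 * x_t
  for (b in seq_len(dim(x_t)[4])) {
    ab <- abar_at(schedule, t[min(b, length(t))])
    out[, , , b] <- (x_t[, , , b] - sqrt(ab) * x0h[, , , b]) / sqrt(1 - ab)
  }
  out
}

#' Assemble a diffusion decoder
#' @param unet a \code{\link{unet_new}} denoiser.
#' @param vae a frozen \code{\link{vae_new}} autoencoder.
#' @param schedule a \code{\link{noise_schedule}}.
#' @return a \code{stw_diffusion} list. \code{latent_scale} (the factor
#'   bringing training latents to unit variance, standard latent-diffusion
#'   practice) is filled in by \code{\link{diffusion_train}}.
#' @export
diffusion_new <- function(unet, vae, schedule = noise_schedule()) {
  structure(list(unet = unet, vae = vae, schedule = schedule,
                 latent_scale = 1),
            class = "stw_diffusion")
}

#' Train the denoiser on encoded latents
#'
#' Standard epsilon-prediction MSE at uniformly sampled steps, with
#' condition dropout (the learned null token) at probability
#' \code{p_uncond}. The VAE must be frozen.
#'
#' @param dd a \code{\link{diffusion_new}} decoder.
#' @param latents (h, w, c, N) array of clean latents.
#' @param conds N x D conditioning matrix (unified embeddings).
#' @param steps,batch_size,lr optimization settings.
#' @param p_uncond condition-dropout probability.
#' @param seed seed for batches, steps, noise and dropout.
#' @return list with the trained \code{dd} and loss \code{trace}.
#' @export
diffusion_train <- function(dd, latents, conds, steps = 400L, batch_size = 8L,
                            lr = 2e-3, p_uncond = 0.1, seed = 1L) {
  if (!isTRUE(dd$vae$frozen)) stop("VAE must be frozen before diffusion training")
  # bring latents to unit variance; the same factor is undone at decode time
  dd$latent_scale <- 1 / stats::sd(latents)
  latents <- latents * dd$latent_scale
  n <- dim(latents)[4]
  params <- collect_params(dd$unet)
  opt <- opt_adamw(params, lr = lr)
  trace <- numeric(steps)
  for (s in seq_len(steps)) {
    dat <- with_seed(seed * 1000L + s, {
      idx <- sample.int(n, min(batch_size, n))
      list(idx = idx,
           t = sample.int(dd$schedule$T, length(idx), replace = TRUE),
           drop = stats::runif(length(idx)) < p_uncond,
           noise = array(stats::rnorm(prod(dim(latents)[1:3]) * length(idx)),
                         c(dim(latents)[1:3], length(idx))))
    })
    xb <- latents[, , , dat$idx, drop = FALSE]
    xt <- 0 * xb
    for (b in seq_along(dat$idx)) {
      xt[, , , b] <- q_sample(xb[, , , b, drop = FALSE], dat$t[b],
                              dat$noise[, , , b, drop = FALSE], dd$schedule)
    }
    cm <- conds[dat$idx, , drop = FALSE]
    zero_grads(params)
    ag_tape_start()
    x0h <- unet_fwd(dd$unet, xt, dat$t, cm, dat$drop, dd$schedule$T)
    loss <- ag_mse(x0h, xb)
    trace[s] <- vv(loss)
    if (!is.finite(trace[s])) { ag_tape_stop(); stop("non-finite diffusion loss") }
    ag_backward(loss)
    ag_tape_stop()
    opt_step(opt)
  }
  list(dd = dd, trace = trace)
}

#' Sample cell images by guided DDIM
#'
#' Deterministic DDIM (eta = 0) from a seeded Gaussian latent. Every step
#' runs the conditional and unconditional branches and combines them by
#' classifier-free guidance; from the second step on, token merging is
#' active in the U-Net self-attention using the previous step's CFG
#' importance, pooled to each attention resolution. The final latent is
#' decoded by the frozen VAE.
#'
#' @param dd a trained \code{\link{diffusion_new}} decoder.
#' @param cond length-D conditioning vector, B x D matrix, or
#'   \code{\link{condition_signal}}.
#' @param steps DDIM steps.
#' @param guidance a \code{\link{guidance_config}} (or numeric w).
#' @param merge_ratio token merge ratio r in [0, 1); 0 disables merging and
#'   reproduces the unmerged computation exactly.
#' @param seed seed for the initial latent.
#' @param telemetry when TRUE, attach a log of token counts before/after
#'   merging per attention layer as attribute \code{"telemetry"}.
#' @param x0_clip clamp on the per-step clean-latent estimate, in units of
#'   the unit-variance training latent scale; keeps early high-noise steps
#'   (where the estimate divides by a tiny sqrt(alpha_bar)) from running
#'   out of distribution (default 3, about the 99.7% range of a
#'   unit-variance latent). NULL disables.
#' @return (H, W, 1, B) decoded images on [0, 1].
#' @export
diffusion_sample <- function(dd, cond, steps = 20L,
                             guidance = guidance_config(3), merge_ratio = 0,
                             seed = 1L, telemetry = FALSE, x0_clip = 3) {
  if (inherits(guidance, "guidance_config")) w <- guidance$w else w <- guidance
  if (inherits(cond, "condition_signal")) cond <- matrix(cond$z_cond, 1L)
  if (!is.matrix(cond)) cond <- matrix(cond, 1L)
  B <- nrow(cond)
  u <- dd$unet
  hw <- 16L
  lat_ch <- u$latent_ch %||% 4L
  x <- with_seed(seed, array(stats::rnorm(hw * hw * lat_ch * B),
                             c(hw, hw, lat_ch, B)))
  ts <- unique(round(seq(dd$schedule$T, 1L, length.out = steps)))
  tel <- if (telemetry) new.env(parent = emptyenv()) else NULL
  if (telemetry) tel$log <- list()
  merge <- NULL
  for (k in seq_along(ts)) {
    t <- ts[k]
    t_next <- if (k < length(ts)) ts[k + 1L] else 0L
    eps_u <- eps_from_x0(dd$schedule, x,
                         vv(unet_fwd(u, x, rep(t, B), cond, rep(TRUE, B),
                                     dd$schedule$T, merge, tel)), rep(t, B))
    eps_c <- eps_from_x0(dd$schedule, x,
                         vv(unet_fwd(u, x, rep(t, B), cond, rep(FALSE, B),
                                     dd$schedule$T, merge, tel)), rep(t, B))
    eps <- cfg_combine(eps_u, eps_c, w)
    ab_t <- abar_at(dd$schedule, t)
    ab_n <- abar_at(dd$schedule, t_next)
    x0 <- (x - sqrt(1 - ab_t) * eps) / sqrt(ab_t)
    if (!is.null(x0_clip)) x0 <- pmin(pmax(x0, -x0_clip), x0_clip)
    x <- sqrt(ab_n) * x0 + sqrt(1 - ab_n) * eps
    if (merge_ratio > 0 && k < length(ts)) {
      s16 <- vector("list", B); s8 <- vector("list", B)
      for (b in seq_len(B)) {
        du <- eps_u[, , , b, drop = FALSE]
        dc <- eps_c[, , , b, drop = FALSE]
        s16[[b]] <- token_importance(du, dc, c(16L, 16L))$scores
        s8[[b]] <- token_importance(du, dc, c(8L, 8L))$scores
      }
      merge <- list(r = merge_ratio, scores16 = s16, scores8 = s8)
    }
  }
  img <- vae_decode(dd$vae, x / (dd$latent_scale %||% 1))
  if (telemetry) attr(img, "telemetry") <- tel$log
  img
}

#' Apply gene perturbations to an expression vector
#'
#' @param g named or unnamed count vector.
#' @param edits named list: \code{list(gene_id = list(mode = "knockout"))}
#'   or \code{list(gene_id = list(mode = "overexpress", factor = 2))}.
#' @param gene_ids ids aligned to \code{g} (defaults to \code{names(g)}).
#' @return the edited vector; entries not named in \code{edits} are
#'   unchanged.
#' @export
perturb_genes <- function(g, edits, gene_ids = names(g)) {
  if (is.null(gene_ids)) stop("gene_ids required")
  gp <- g
  for (id in names(edits)) {
    j <- match(id, gene_ids)
    if (is.na(j)) stop("unknown gene id: ", id)
    e <- edits[[id]]
    if (e$mode == "knockout") {
      gp[j] <- 0
    } else if (e$mode == "overexpress") {
      gp[j] <- gp[j] * e$factor
    } else if (e$mode == "knockdown") {
      gp[j] <- gp[j] * (e$factor %||% 0.5)
    } else stop("unknown edit mode: ", e$mode)
  }
  gp
}
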