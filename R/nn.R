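# Transformer building blocks on top of the autograd engine.
# All layers are plain lists of parameter nodes plus forward functions; the
# same forward code serves training (tape on) and inference (tape off).

#' @noRd
rmat <- function(n, m, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (n + m))
  matrix(stats::rnorm(n * m, sd = sd), n, m)
}

#' @noRd
linear_new <- function(d_in, d_out, sd = NULL) {
  list(W = ag_param(rmat(d_in, d_out, sd)), b = ag_param(numeric(d_out)))
}

#' @noRd
linear_fwd <- function(lin, x) ag_add(ag_matmul(x, lin$W), lin$b)

#' @noRd
layernorm_new <- function(d) {
  list(gamma = ag_param(rep(1, d)), beta = ag_param(numeric(d)))
}

#' @noRd
ln_fwd <- function(ln, x) ag_layernorm(x, ln$gamma, ln$beta)

#' @noRd
mha_new <- function(d, n_heads) {
  stopifnot(d %% n_heads == 0L)
  list(Wq = linear_new(d, d), Wk = linear_new(d, d), Wv = linear_new(d, d),
       Wo = linear_new(d, d), n_heads = n_heads, d = d)
}

# Scaled dot-product multi-head attention. Q: n_q x d, K/V: n_k x d.
# Returns list(out = n_q x d, weights = list of per-head n_q x n_k matrices).
#' @noRd
mha_fwd <- function(p, Qin, Kin, Vin) {
  h <- p$n_heads
  dh <- p$d %/% h
  Q <- linear_fwd(p$Wq, Qin)
  K <- linear_fwd(p$Wk, Kin)
  V <- linear_fwd(p$Wv, Vin)
  outs <- vector("list", h)
  wts <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    Qh <- ag_cols(Q, cols)
    Kh <- ag_cols(K, cols)
    Vh <- ag_cols(V, cols)
    A <- ag_softmax_rows(ag_scale(ag_matmul(Qh, ag_t(Kh)), 1 / sqrt(dh)))
    wts[[i]] <- A
    outs[[i]] <- ag_matmul(A, Vh)
  }
  out <- linear_fwd(p$Wo, ag_cbind(outs))
  list(out = out, weights = wts)
}

# Pre-norm transformer encoder block (self-attention + MLP, residuals).
#' @noRd
block_new <- function(d, n_heads, mlp_ratio = 4L) {
  list(ln1 = layernorm_new(d), attn = mha_new(d, n_heads),
       ln2 = layernorm_new(d),
       fc1 = linear_new(d, d * mlp_ratio), fc2 = linear_new(d * mlp_ratio, d))
}

#' @noRd
block_fwd <- function(blk, x) {
  h <- ln_fwd(blk$ln1, x)
  x <- ag_add(x, mha_fwd(blk$attn, h, h, h)$out)
  h2 <- ln_fwd(blk$ln2, x)
  ag_add(x, linear_fwd(blk$fc2, ag_gelu(linear_fwd(blk$fc1, h2))))
}

# Pre-norm cross-attention block: queries attend to an external key/value
# sequence, with residual and feed-forward.
#' @noRd
xblock_new <- function(d, n_heads, mlp_ratio = 2L) {
  list(lnq = layernorm_new(d), lnk = layernorm_new(d),
       attn = mha_new(d, n_heads), ln2 = layernorm_new(d),
       fc1 = linear_new(d, d * mlp_ratio), fc2 = linear_new(d * mlp_ratio, d))
}

#' @noRd
xblock_fwd <- function(blk, q, kv) {
  kn <- ln_fwd(blk$lnk, kv)
  x <- ag_add(q, mha_fwd(blk$attn, ln_fwd(blk$lnq, q), kn, kn)$out)
  h <- ln_fwd(blk$ln2, x)
  ag_add(x, linear_fwd(blk$fc2, ag_gelu(linear_fwd(blk$fc1, h))))
}

# Fixed 2-D sinusoidal positional embeddings for integer grid coordinates.
# Half of the channels encode the row, half the column.
#' @noRd
sinusoidal_2d <- function(grid, d) {
  stopifnot(d %% 4 == 0L)
  q <- d %/% 4L
  freq <- 1 / (100^((seq_len(q) - 1) / q))
  enc1 <- function(v) {
    ang <- outer(v, freq)
    cbind(sin(ang), cos(ang))
  }
  cbind(enc1(grid[, 1, drop = TRUE]), enc1(grid[, 2, drop = TRUE]))
}

# Sinusoidal timestep embedding (vector of steps -> length(t) x d matrix).
#' @noRd
timestep_embedding <- function(t, d) {
  half <- d %/% 2L
  freq <- exp(-log(10000) * (seq_len(half) - 1) / half)
  ang <- outer(t, freq)
  emb <- cbind(sin(ang), cos(ang))
  if (ncol(emb) < d) emb <- cbind(emb, 0)
  emb
}
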