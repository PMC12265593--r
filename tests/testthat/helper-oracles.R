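# Independent oracles used across tests. These are deliberately written as
# direct loop/closed-form computations, sharing no code with the package's
# vectorized implementations.

# Dense multi-head scaled dot-product attention, computed head by head with
# explicit loops over queries and keys.
oracle_attention <- function(Q, K, V, params) {
  h <- params$n_heads
  d <- params$d
  dh <- d / h
  proj <- function(x, lin) x %*% lin$W$v + matrix(lin$b$v, nrow(x), d, byrow = TRUE)
  Qp <- proj(Q, params$Wq); Kp <- proj(K, params$Wk); Vp <- proj(V, params$Wv)
  out <- matrix(0, nrow(Q), 0)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * dh + 1):(i * dh)
    oh <- matrix(0, nrow(Q), dh)
    for (q in seq_len(nrow(Q))) {
      logits <- numeric(nrow(K))
      for (k in seq_len(nrow(K))) {
        logits[k] <- sum(Qp[q, cols] * Kp[k, cols]) / sqrt(dh)
      }
      w <- exp(logits - max(logits))
      w <- w / sum(w)
      for (k in seq_len(nrow(K))) oh[q, ] <- oh[q, ] + w[k] * Vp[k, cols]
    }
    out <- cbind(out, oh)
  }
  out %*% params$Wo$W$v + matrix(params$Wo$b$v, nrow(Q), d, byrow = TRUE)
}

# Pre-norm cross-attention block oracle mirroring the published fusion rule:
# layernorm, attention, residual, layernorm, gelu MLP, residual — all from
# scratch with plain arithmetic.
oracle_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  t(apply(x, 1, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps) * gamma + beta
  }))
}

oracle_xblock <- function(blk, q, kv) {
  kn <- oracle_layernorm(kv, blk$lnk$gamma$v, blk$lnk$beta$v)
  qn <- oracle_layernorm(q, blk$lnq$gamma$v, blk$lnq$beta$v)
  x <- q + oracle_attention(qn, kn, kn, blk$attn)
  h <- oracle_layernorm(x, blk$ln2$gamma$v, blk$ln2$beta$v)
  h1 <- h %*% blk$fc1$W$v + matrix(blk$fc1$b$v, nrow(h), ncol(blk$fc1$W$v), byrow = TRUE)
  h1 <- h1 * pnorm(h1)
  x + h1 %*% blk$fc2$W$v + matrix(blk$fc2$b$v, nrow(h), ncol(blk$fc2$W$v), byrow = TRUE)
}

# Brute-force minimal covering square: smallest integer S such that some
# axis-aligned S x S square contains all vertices.
oracle_min_square_side <- function(boundary) {
  w <- max(boundary[, 1]) - min(boundary[, 1])
  h <- max(boundary[, 2]) - min(boundary[, 2])
  S <- 0L
  repeat {
    S <- S + 1L
    if (S >= w && S >= h) return(S)
  }
}

# random star-convex polygon (same guarantees as the generator, independent
# construction)
random_polygon <- function(cx, cy, rmin = 2, rmax = 18, nv = 5:16) {
  n <- sample(nv, 1)
  ang <- sort(runif(n, 0, 2 * pi))
  rad <- runif(n, rmin, rmax)
  cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
}

# point-in-polygon by ray casting (used to check rendered geometry)
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# small default slide fixture used by several files
tiny_slide_config <- function(seed = 7L, n_cells = 50L, n_types = 3L,
                              n_genes = 20L, px = 256L, noise = 0.02) {
  synthetic_config(n_cell_types = n_types, n_genes = n_genes,
                   slide_height = px, slide_width = px, n_z_planes = 3L,
                   n_cells = n_cells, niche_mixing = 0.1,
                   background_noise = noise, seed = seed)
}

tiny_model_config <- function(n_genes = 20L, d = 16L, seed = 1L) {
  stw_config(embed_dim = d, n_heads = 4L, depth = 1L, n_genes = n_genes,
             cell_input_px = 32L, cell_patch_px = 8L, niche_input_px = 32L,
             niche_patch_px = 8L, recon_px = 16L, seed = seed)
}
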